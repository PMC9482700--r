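# sfproj — spherical frame projections for joint range of motion

Quantifying the range of motion (RoM) of a 3-degree-of-freedom joint
means describing a *region* of the rotation group, not three scalar
angle ranges: how far a joint can rotate about one axis depends on
where the other axes currently point.  `sfproj` implements the
spherical frame projection (SFP), a visualisation and analysis of
exactly that structure, for biomechanists working with joint
orientation data from motion capture, XROMM-style bone kinematics, or
simulation.

## The core idea

A joint pose is the rotation `R ∈ SO(3)` of the distal bone's
anatomical coordinate system (ACS) in the proximal bone's.  In the row
convention used throughout, row *i* of `R` is the unit endpoint of the
distal frame's *i*-th axis expressed in proximal coordinates.  For an
RoM dataset `{R_k}`, plotting the rows of every matrix traces three
point clouds on the unit sphere — one per frame axis.  Fitting a closed
spherical polygon around each cloud yields the SFP: a triplet of
boundary regions around the null-pose frame in which each axis
endpoint must remain.  Each polygon is fitted as the outer perimeter of
the occupied patches of a subdivided-icosahedron grid (1,280 patches by
default), so the fit is reproducible and resolution-controlled, and
every data point is inside its polygon by construction.

Around that core the package provides rotation representations (Euler
sequences, quaternions, axis-angle), spherical geometry (geodesic arcs,
Gauss–Bonnet polygon areas, point-in-polygon tests), pose-viability
checks (per-axis membership plus a stronger path-connectivity check),
pose-space coverage accounting with three-pass saturation, the full
homogeneous-transform chain from motion-capture marker poses to
joint-centric orientations (Procrustes rigid-body fits, plate and bone
frame fitting, recursive cross-product orthogonalisation), and a
synthetic RoM / capture-rig simulator that supplies ground truth for
every stage.

## A worked example

Generate a 2-DoF joint with independent ±30° and ±15° ranges, fit its
SFP, and query poses:

```r
library(sfproj)

rom <- generate_rom(rom_spec("two_dof", half_ranges = c(30, 15),
                             axes = c("X", "Y"), step = 2.5))
fit <- sfp(rom)
summary(fit)
#> Spherical frame projection of 325 orientations [synthetic two_dof RoM]
#> Occupancy grid: 1280 patches (3 subdivisions, ~9.44 deg patch width), dilation 0
#>  axis vertices occupied_patches solid_angle_sr cloud_diameter_deg
#>     X       14               18         0.1720              30.00
#>     Y       16               16         0.1738              60.00
#>     Z       32               68         0.6504              66.45
```

The X cloud spans 30° (it only moves under the ±15° Y rotation), the Y
cloud spans 60°, and the Z polygon is the 60° × 30° rectangle on the
sphere whose sides are the two Euler ranges.  Membership and
reachability checks:

```r
check_pose(fit, from_euler(c(10, 5), "XY"))
#> $x          TRUE
#> $y          TRUE
#> $z          TRUE
#> $all_inside TRUE
#> $note       "all_inside is necessary but not sufficient for reachability"

check_pose_path(rom, from_euler(c(0, 0), "XY"),
                from_euler(c(25, -10), "XY"), step_max = 10)$viable
#> [1] TRUE
```

`plot(fit)` (or `render_sfp(fit, "sfp.png")`) draws the three polygons
on the sphere — X red, Y green, Z blue — with the null-pose frame at
the centre; `write_sfp()` / `export_sfp_obj()` export to JSON and OBJ.

A command-line front end covers the pipeline end to end
(`simulate`, `transform`, `project`, `fit-boundary`, `check-pose`,
`check-path`, `coverage`, `render`); run `exec/sfp` with no arguments
for usage.

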