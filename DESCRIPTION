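Package: sfproj
Title: Spherical Frame Projections for Joint Range of Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Visualise and quantify three-degree-of-freedom joint range of
    motion with spherical frame projections (SFPs): the rows of each
    relative rotation matrix are traced as points on the unit sphere and a
    triplet of spherical boundary polygons is fitted around the three axis
    clouds.  Includes rotation-representation utilities (Euler sequences,
    quaternions, axis-angle), occupancy-grid boundary fitting on a
    subdivided icosahedron, spherical polygon area and point-in-polygon
    tests, path-based pose-viability checks, pose-space coverage
    accounting, the homogeneous-transform chain from motion-capture marker
    poses to joint-centric orientations (plate and bone frame fitting with
    recursive cross-product orthogonalisation), and a synthetic range of
    motion and capture-rig simulator that provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
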