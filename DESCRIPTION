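Package: pocketgrid
Title: Geometric Detection of Protein Ligand-Binding Pockets by Convex Hull
    Facets and Voxel Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts and characterises ligand-binding pockets on a protein
    surface from its atomic coordinates alone. The structure's bounding box is
    voxelised at 1 Angstrom resolution, the convex hull of the atom centers is
    triangulated, and every hull facet seeds a candidate pocket made of the
    atoms closest to that facet together with the empty voxels around them.
    Candidate pockets are merged by an asymmetric atom-overlap criterion,
    profiled by per-atom biochemical interaction classes (hydrogen-bond
    donors/acceptors, van der Waals, ionic, sulfur, carbon rings), filtered
    against the physical dimensions of a ligand, and scored against the active
    sites declared in a liganded partner structure via the correct-fraction
    (cf) statistic. Includes PDB input/output (ATOM/HETATM via 'bio3d', plus
    SITE, CONECT and REMARK 800 records), a deterministic synthetic-structure
    generator with a planted concave cavity for end-to-end testing, tidy
    tibble-based results with broom-style tidy()/glance() methods, ggplot2
    autoplot() methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
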