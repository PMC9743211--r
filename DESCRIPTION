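Package: backmapr
Title: Time-Aware Generative Backmapping of Coarse-Grained Molecular
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs atomistic detail for coarse-grained (CG)
    molecular dynamics trajectories in a temporally coherent way. A
    conditional variational autoencoder is trained on voxelized Gaussian
    particle-density representations of sequential trajectory frames to
    model the distribution of atomistic structures consistent with the
    current CG frame and the previously reconstructed atomistic frame,
    and is then rolled out autoregressively to backmap whole CG
    trajectories. Includes the coarse-graining machinery (atom-index
    slicing maps for alanine-dipeptide- and chignolin-style schemes), a
    composite reconstruction loss with annealed energy and KL terms, an
    ex-post Gaussian-mixture latent prior, a bead-spring Langevin toy
    simulator with metastable torsional states for desk-scale testing,
    and an evaluation battery covering energy distributions, dihedral-
    and TICA-basis free-energy surfaces, Markov state model implied
    timescales, eigenvector similarity, and finite-difference velocity
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    mclust,
    yaml,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
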