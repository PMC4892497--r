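Package: trajshape
Title: Shape-Respecting Clustering of Longitudinal Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters longitudinal trajectories by shape. The distance between
    two trajectories is a time-scaled (generalized) Frechet distance computed by
    dynamic programming over monotone couplings; cluster centres are Frechet
    means obtained by averaging curves along the optimal coupling path. A
    k-means style partitioning loop (kmlShape) alternates Frechet assignment
    and Frechet-mean updates. For large datasets two reduction steps are
    provided: election of weighted representative trajectories ("senators")
    via Euclidean k-means, and Douglas-Peucker trajectory simplification with
    either an error or a point-budget stopping rule. The package also ships a
    synthetic longitudinal data generator with Gaussian-density and
    Gaussian-CDF group templates, partition agreement metrics (correct
    classification rate, adjusted Rand index) and a simulation-study driver.
License: MIT
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics, grDevices, e1071
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
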