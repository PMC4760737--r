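Package: gutabm
Title: Agent-Based Simulation of a Two-Species Gut Microbial Community
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An individual-based model of two cross-feeding bacterial
    species in a two-dimensional virtual gut. Bacteria ferment dietary and
    host polysaccharides to the short-chain fatty acids acetate, propionate
    and butyrate; passive metabolite particles are advected along the gut,
    absorbed at the wall through saturable monocarboxylate transport, and
    excreted at the outlet. Seven feedback mechanisms (toxin-antitoxin
    coupling, bacterial and gut-mediated toxin production, host feeding)
    can be enabled to stabilize the community. Antibiotic courses perturb
    the system, and resistance evolves by mutation at division with a
    growth-rate fitness cost. The analysis layer computes spatial
    segregation indices, density profiles, recovery and resilience times,
    bistability mode counts, and post-treatment resistance outcome classes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    MASS
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
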