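Package: congressr
Title: Quantitative Analysis of Chromosome Congression from Tracked
    Kinetochore Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify chromosome congression in mitotic cells from
    tracked spindle-pole and sister-kinetochore trajectories. Reconstructs
    the spindle reference frame (pole axis, midpoint, equatorial plane),
    computes per-frame pair kinematics (distance to plane and nearest pole,
    interkinetochore distance, positional and orientation angles),
    classifies polar versus aligned kinetochore pairs, detects metaphase
    plate crossings and windowed congression velocities, and summarises
    alignment success, polar-chromosome counts over time, misalignment
    categories and maximum chromosome spread per cell. Also quantifies
    kinetochore fluorescence on sum projections with cytoplasmic background
    subtraction and reference-channel and within-cell normalization,
    provides the group-comparison statistics used in such studies (one-way
    ANOVA with Tukey HSD, two-proportion z, chi-square, OLS regression,
    confidence intervals of mean and standard deviation), and ships a
    synthetic-data generator producing biphasic congression trajectories,
    checkpoint-protein intensity decay and Gaussian-spot image stacks with
    known ground truth for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    readr,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
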