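Package: sprintcoord
Title: Segment Coordination Analysis for Initial Sprint Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing inter- and intra-limb segment coordination
    during the initial steps of sprint acceleration. Takes sagittal-plane
    segment angle time series (trunk, thighs, shanks, feet) with gait event
    annotations, segments trials into steps (toe-off to contralateral
    toe-off), time-normalizes each step, and applies a modified vector
    coding analysis: coupling angles from angle-angle diagrams, an
    eight-bin coordination classification (phase relationship, rotation
    direction, dominant segment), and segment dominancy percentages via
    gradian conversion. Provides group-level circular statistics (circular
    mean profiles, between-individual angular deviation), coordination bin
    frequencies, a step-to-step coupling-angle difference score (CA_Diff),
    and an inferential layer (repeated-measures ANOVA with
    Greenhouse-Geisser correction, Friedman and Wilcoxon signed-rank tests
    with Bonferroni adjustment). Includes a synthetic multi-step sprint
    kinematics generator with known coordination ground truth, a plotting
    layer for coordination profiles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
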