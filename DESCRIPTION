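Package: pinkstim
Title: Dynamic Pink-Noise Stimuli for Item-Free Visual Attention Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesis and analysis tools for a dynamic 1/f ("pink") noise
    protocol used to probe visual attention without localized test items.
    Generates seeded full-field pink-noise movies in the frequency domain,
    embeds an orientation-filtered local discrimination signal of adjustable
    strength through a raised-cosine window, assembles cued and uncued trial
    sequences, and analyses two-alternative forced-choice responses with
    maximum-likelihood cumulative-Gaussian psychometric fits, 75%-threshold
    extraction, and within-observer permutation tests. A simulated observer
    and an image-computable orientation-energy decoder close the loop
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    rlang,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
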