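Package: ratioherit
Title: Distribution and Heritability of Ratio Traits from Correlated
    Component Traits
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo machinery for studying ratio traits such as feed
    efficiency or fat percentage, whose numerator and denominator are
    correlated, normally distributed component traits. Simulates
    two-generation pedigreed populations with Mendelian sampling through
    Cholesky factors of the genetic and environmental covariance matrices,
    characterises the ratio trait's distribution by its first four moments,
    estimates its heritability from midparent-offspring statistics, and
    provides delta-method closed forms for the ratio trait's mean, variance
    and heritability. Includes grid-experiment drivers with replication and
    CSV summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), e1071, jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
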