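Package: radiofuse
Title: Fused Imaging Feature Signatures and Radiogenomic Association
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds fused radiomic feature signatures from tumour CT-like
    volumes and relates them to gene expression. Provides a synthetic
    phantom/expression cohort generator with planted, recoverable
    radiogenomic structure; 2.5D multiplanar tumour views; handcrafted
    radiomics (first-order, shape, grey-level co-occurrence and wavelet-band
    features); a deterministic filter-bank stand-in for deep feature
    extractors; three-stage signature selection (median-absolute-deviation
    filtering, minimum-redundancy maximum-relevance selection, and
    cross-validated multinomial LASSO); patient clustering and tumour-stage
    association; quartile-based gene filtering; Spearman radiogenomics
    relationship calling; and pre-ranked gene-set enrichment with
    permutation-normalised enrichment scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
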