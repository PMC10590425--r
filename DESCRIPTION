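Package: esdflow
Title: Surgical Workflow Recognition and Skill Analytics for Endoscopic
    Submucosal Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-level recognition of the four endoscopic submucosal
    dissection (ESD) workflow phases (Marking, Injection, Dissection, Idle)
    from endoscopy video. Provides the full modelling stack: a frame-wise
    spatial encoder trained with a combined supervised-contrastive and
    cross-entropy objective, a causal dilated temporal convolution network,
    and a scaled dot-product attention head producing per-frame phase
    probabilities; a bounded-memory streaming inference engine built on a
    FIFO queue of spatial embeddings; chronological cross-validation and
    two-stage training orchestration; evaluation statistics (confusion
    matrices, ROC/AUROC, Youden-index operating points, specificity,
    sensitivity, orderliness, Student-t confidence intervals); and skill
    analytics (phase-transition matrices, the normalized-transition NT-index,
    phase periods and derived ratios) with automatic structured report
    generation. A synthetic phase-labelled video generator with controllable
    skill profiles makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
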