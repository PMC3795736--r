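Package: diracnet
Title: Rank-Conservation Analysis of Gene Networks Across Ordered Tumor Grades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential rank conservation (DIRAC) analysis of gene-expression
    cohorts spanning ordered disease phenotypes, motivated by multi-study
    astrocytoma grading (normal, grade 2, grade 3, primary and secondary
    glioblastoma). Implements within-array rank preprocessing (present-call
    filtering, probe-to-gene collapse, rank transform, correlation QC), network
    rank templates and matching scores, per-phenotype conservation indices and
    global dysregulation summaries, permutation tests for differentially
    regulated networks, template-based two-class network classification with
    leave-one-out cross-validation and pooled-permutation FDR, and detection of
    genes changing monotonically with grade (adjacent-grade Wilcoxon DEG
    intersection, subsampling robustness, directionality permutation test). A
    synthetic multi-batch cohort generator with planted ground truth makes the
    whole pipeline testable without external microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
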