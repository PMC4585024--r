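Package: viromeval
Title: Evaluation of Viral Metagenome Assemblies with Known Read Provenance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates abundance-weighted viral metagenome paired-end reads with
    per-read provenance, builds the best attainable ("ideal") assembly by merging
    overlapping read intervals per genome, emulates assembler degradation
    (read loss, contig splitting, chimera formation), and quantifies assembly
    quality through an assembly-statistics panel (N50, reads assembled, contig
    coverage, chimera rates across taxonomic ranks, genome fragmentation score,
    penalized coverage). Alpha diversity (Shannon, Chao1, ACE, species number)
    is computed under contig-as-OTU and species-as-OTU accounting, and assembly
    statistics are linked to diversity with Spearman correlation, L1-regularized
    regression and random-forest permutation importance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    Biostrings,
    glmnet,
    randomForest,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
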