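Package: lncfun
Title: Functional Annotation of Long Non-Coding RNAs by Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates human long non-coding RNAs (lncRNAs) with Gene Ontology
    terms and biological pathways by guilt-by-association. Pearson correlations
    between lncRNA and protein-coding expression profiles across a tissue panel
    define, for each lncRNA, a set of significantly co-expressed coding genes;
    hypergeometric enrichment of that set against GO (with annotation
    propagation up the ontology) and flat pathway collections, corrected by the
    Benjamini-Yekutieli or Benjamini-Hochberg procedure, yields the functional
    annotation. Includes readers for expression matrices, gene catalogs (TSV or
    GTF), OBO ontologies, GAF annotation files and GMT gene sets; a set-level
    analysis with a minimum co-expression support parameter; a synthetic
    fixture generator with planted co-expression modules for validation; and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
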