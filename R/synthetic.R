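#' Configuration for the synthetic fixture generator
#'
#' The generator emulates the structure of a multi-tissue expression panel:
#' 19 conditions by default, with planted modules in which a few lncRNAs and
#' a block of protein-coding genes share a latent condition profile. Member
#' genes are `s * latent + noise` with `s` chosen so the expected pairwise
#' Pearson correlation between members is `rho = s^2 / (s^2 + noise_sd^2)`.
#' Background genes are independent noise. Setting `rho = NA` produces a null
#' fixture in which every gene is independent.
#'
#' @param n_conditions Number of conditions (tissues), default 19.
#' @param n_modules Number of planted modules, default 5.
#' @param coding_per_module Coding genes per module, default 20 (so every
#'   planted term has M well above the minimum-size filter of 5).
#' @param lnc_per_module lncRNAs per module, default 3.
#' @param n_background_coding,n_background_lnc Independent background genes,
#'   defaults 200 and 20.
#' @param rho Target within-module Pearson correlation in (0, 1), default
#'   0.95; `NA` for a null fixture.
#' @param noise_sd Noise standard deviation, default 1.
#' @param seed Integer seed; mandatory, the generator never uses implicit
#'   global RNG state.
#' @param nonneg How expression values are made non-negative: `"shift"`
#'   (subtract the global minimum; Pearson correlation is
#'   translation-invariant, so planted correlations are untouched) or
#'   `"exp"` (`2^x`).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_conditions = 19L, n_modules = 5L,
                           coding_per_module = 20L, lnc_per_module = 3L,
                           n_background_coding = 200L, n_background_lnc = 20L,
                           rho = 0.95, noise_sd = 1, seed,
                           nonneg = c("shift", "exp")) {
  if (missing(seed)) stop("a seed is mandatory")
  nonneg <- match.arg(nonneg)
  cfg <- list(n_conditions = as.integer(n_conditions),
              n_modules = as.integer(n_modules),
              coding_per_module = as.integer(coding_per_module),
              lnc_per_module = as.integer(lnc_per_module),
              n_background_coding = as.integer(n_background_coding),
              n_background_lnc = as.integer(n_background_lnc),
              rho = rho, noise_sd = noise_sd, seed = as.integer(seed),
              nonneg = nonneg)
  with(cfg, {
    if (n_conditions < 3L) stop("need at least 3 conditions")
    if (n_modules < 1L || coding_per_module < 1L || lnc_per_module < 1L)
      stop("module counts must be >= 1")
    if (n_background_coding < 0L || n_background_lnc < 0L)
      stop("background counts must be >= 0")
    if (!is.na(rho) && (rho <= 0 || rho >= 1))
      stop("rho must be in (0, 1), or NA for a null fixture")
    if (noise_sd <= 0) stop("noise_sd must be > 0")
  })
  structure(cfg, class = "fixture_config")
}

# Run fn() under a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a synthetic fixture with known ground truth
#'
#' Produces an expression matrix with planted lncRNA-mRNA co-expression
#' modules, a matching gene catalog, a toy ontology (one root, one leaf term
#' per module), direct annotations of each module's coding genes to its leaf
#' term, one pathway per module, and the planted truth. Fully reproducible:
#' the same config (including seed) yields identical output.
#'
#' @param config A [fixture_config()].
#' @return An `lnc_fixture` list: `expression`, `catalog`, `ontology`,
#'   `annotations` (direct only; propagate before use), `pathways`, `truth`,
#'   `config`.
#' @export
generate_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, function() generate_fixture_impl(config))
}

generate_fixture_impl <- function(cfg) {
  tt <- cfg$n_conditions
  conditions <- sprintf("tissue_%02d", seq_len(tt))
  null_fixture <- is.na(cfg$rho)
  s <- if (null_fixture) 0 else cfg$noise_sd * sqrt(cfg$rho / (1 - cfg$rho))
  total_sd <- sqrt(s^2 + cfg$noise_sd^2)

  rows <- list()
  truth <- vector("list", cfg$n_modules)
  for (j in seq_len(cfg$n_modules)) {
    latent <- stats::rnorm(tt)
    coding_ids <- sprintf("PCG_M%d_%03d", j, seq_len(cfg$coding_per_module))
    lnc_ids <- sprintf("LNC_M%d_%02d", j, seq_len(cfg$lnc_per_module))
    for (id in c(coding_ids, lnc_ids))
      rows[[id]] <- s * latent + stats::rnorm(tt, sd = cfg$noise_sd)
    truth[[j]] <- list(
      module = j, lncrna_ids = lnc_ids, coding_ids = coding_ids,
      go_term = sprintf("MOD:%07d", j),
      pathway = sprintf("SYNTH::module_%d_pathway", j))
  }
  for (id in sprintf("PCG_BG_%03d", seq_len(cfg$n_background_coding)))
    rows[[id]] <- stats::rnorm(tt, sd = total_sd)
  for (id in sprintf("LNC_BG_%03d", seq_len(cfg$n_background_lnc)))
    rows[[id]] <- stats::rnorm(tt, sd = total_sd)

  values <- do.call(rbind, rows)
  colnames(values) <- conditions
  values <- if (cfg$nonneg == "shift") values - min(values) else 2^values
  validate_expression_matrix(values)

  biotype <- ifelse(startsWith(rownames(values), "PCG_"), "protein_coding", "lncRNA")
  catalog <- stats::setNames(biotype, rownames(values))

  root <- "MOD:0000000"
  leaf_ids <- vapply(truth, `[[`, character(1L), "go_term")
  dag <- structure(
    list(terms = data.frame(
           id = c(root, leaf_ids),
           name = c("synthetic_root",
                    sprintf("synthetic_module_%d", seq_len(cfg$n_modules))),
           namespace = "biological_process", stringsAsFactors = FALSE),
         edges = data.frame(child = leaf_ids, parent = root, type = "is_a",
                            stringsAsFactors = FALSE),
         obsolete = character(0)),
    class = "ontology_dag")

  direct <- stats::setNames(lapply(truth, `[[`, "coding_ids"), leaf_ids)
  ann <- annotation_set(direct = direct, dag = dag)

  pw_names <- sprintf("module_%d_pathway", seq_len(cfg$n_modules))
  pw_keys <- paste0("SYNTH::", pw_names)
  pathways <- structure(
    list(meta = data.frame(key = pw_keys, database = "SYNTH", name = pw_names,
                           stringsAsFactors = FALSE),
         sets = stats::setNames(lapply(truth, function(m) sort(m$coding_ids)),
                                pw_keys)),
    class = "pathway_collection")

  structure(list(expression = values, catalog = catalog, ontology = dag,
                 annotations = ann, pathways = pathways, truth = truth,
                 config = cfg),
            class = "lnc_fixture")
}

#' Write a fixture bundle to disk in standard formats
#'
#' Emits `expression.tsv`, `catalog.tsv`, `ontology.obo`, `annotations.gaf`,
#' `pathways.gmt` and `truth.json`, all readable by this package's parsers.
#' Refuses to write into a non-empty directory unless `force = TRUE`.
#'
#' @param fixture An `lnc_fixture` from [generate_fixture()].
#' @param dir Output directory (created if missing).
#' @param force Overwrite into a non-empty directory.
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir, force = FALSE) {
  stopifnot(inherits(fixture, "lnc_fixture"))
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("directory ", dir, " is not empty (use force = TRUE to overwrite)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(fixture$expression, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(gene_id = names(fixture$catalog), biotype = fixture$catalog),
    file.path(dir, "catalog.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_obo(fixture$ontology, file.path(dir, "ontology.obo"))
  write_gaf(fixture$annotations, file.path(dir, "annotations.gaf"))
  write_gmt(fixture$pathways, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(
    lapply(fixture$truth, function(m)
      list(module = m$module, lncrna_ids = m$lncrna_ids,
           coding_ids = m$coding_ids, go_term = m$go_term,
           pathway = m$pathway)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  parents <- split(dag$edges$parent[dag$edges$type == "is_a"],
                   dag$edges$child[dag$edges$type == "is_a"])
  po <- split(dag$edges$parent[dag$edges$type == "part_of"],
              dag$edges$child[dag$edges$type == "part_of"])
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i]),
                 if (!is.null(parents[[id]])) paste0("is_a: ", parents[[id]]),
                 if (!is.null(po[[id]])) paste0("relationship: part_of ", po[[id]]),
                 ""), con)
  }
  for (id in dag$obsolete)
    writeLines(c("[Term]", paste0("id: ", id), "is_obsolete: true", ""), con)
  invisible(path)
}

write_gaf <- function(ann, path) {
  aspect_map <- c(biological_process = "P", molecular_function = "F",
                  cellular_component = "C")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  ns <- stats::setNames(ann$terms$namespace, ann$terms$id)
  for (term in names(ann$direct)) {
    aspect <- aspect_map[unname(ns[term])]
    if (is.na(aspect)) aspect <- "P"
    for (gene in ann$direct[[term]]) {
      writeLines(paste(c("SYNTH", gene, gene, "", term, "SYNTH:0000001",
                         "EXP", "", aspect, gene, "", "gene", "taxon:9606",
                         "20260101", "SYNTH", "", ""), collapse = "\t"), con)
    }
  }
  invisible(path)
}

write_gmt <- function(pathways, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(pathways$meta))) {
    key <- pathways$meta$key[i]
    writeLines(paste(c(pathways$meta$name[i], pathways$meta$database[i],
                       pathways$sets[[key]]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a fixture bundle back from disk
#'
#' Round-trip counterpart of [write_fixture()], using the package's own
#' parsers.
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `expression`, `catalog`, `ontology`, `annotations`,
#'   `pathways`, `truth`.
#' @export
read_fixture <- function(dir) {
  dag <- parse_obo(file.path(dir, "ontology.obo"))
  list(
    expression = read_expression_tsv(file.path(dir, "expression.tsv")),
    catalog = read_gene_catalog(file.path(dir, "catalog.tsv")),
    ontology = dag,
    annotations = parse_gaf(file.path(dir, "annotations.gaf"), dag),
    pathways = parse_gmt(file.path(dir, "pathways.gmt")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE, simplifyDataFrame = FALSE)
  )
}
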