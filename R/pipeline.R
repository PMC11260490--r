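#' Run the full TFCR analysis pipeline from one configuration
#'
#' Orchestrates synthesise/ingest -> TFCR calling -> annotation ->
#' dynamics -> evolution -> RegulatoryScore -> (optional) ML, writing
#' every stage output plus a checksum manifest. The same configuration
#' and seed always produce identical checksums; each module draws its
#' randomness from a child seed derived by stable hashing of the
#' module name, so toggling one module never shifts another's stream.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \preformatted{
#' seed: 1
#' output_dir: out
#' synth:               # synthetic input (or provide 'inputs:')
#'   n_genes: 200
#'   n_stages: 3
#' inputs:              # real input mode
#'   chrom_sizes: genome.chrom.sizes
#'   genes: genes.tsv
#'   hits: [s1.bed, s2.bed]       # per-stage motif-hit BED6+2
#'   expression: [e1.tsv, e2.tsv] # per-stage expression TSV
#' caller: {bandwidth_h: 300, contribution_threshold: 0.1}
#' modules: {annotate: true, dynamics: true, evolution: true,
#'           regscore: true, ml: false}
#' ml: {L_p: 200, L_t: 400, method: gbdt, iterations: 50, depth: 4}
#' }
#'
#' @param config path to a YAML file, or a list with the same shape.
#' @return invisibly, the manifest data.frame (`file`, `stage`,
#'   `checksum`); also written as `manifest.tsv`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_pipeline_config(cfg)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(path, stage) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = basename(path), stage = stage,
      checksum = digest::digest(file = path, algo = "md5"),
      stringsAsFactors = FALSE)
  }

  # ---- inputs -------------------------------------------------------
  if (!is.null(cfg$synth)) {
    sargs <- cfg$synth
    sargs$seed <- child_seed(cfg$seed, "synth")
    scfg <- do.call(synth_config, sargs)
    ds <- make_dataset(scfg, make_sequence = isTRUE(cfg$modules$ml))
    assembly <- ds$assembly
    genes <- ds$genes
    stage_hits <- lapply(ds$stages, `[[`, "hits")
    names(stage_hits) <- vapply(ds$stages, `[[`, character(1), "stage_id")
    stage_expr <- lapply(ds$stages, `[[`, "expression")
    sequence <- ds$sequence
  } else {
    inp <- cfg$inputs
    assembly <- read_chrom_sizes(inp$chrom_sizes)
    genes <- read_gene_models(inp$genes, assembly = assembly)
    stage_hits <- lapply(inp$hits, read_motif_hits, format = "bed",
                         p_threshold = inp$p_threshold %||% 1e-5)
    names(stage_hits) <- sprintf("stage%02d", seq_along(stage_hits))
    stage_expr <- if (!is.null(inp$expression)) {
      lapply(inp$expression, read_expression)
    } else NULL
    sequence <- if (!is.null(inp$fasta)) {
      Biostrings::readDNAStringSet(inp$fasta)
    } else NULL
  }

  # ---- TFCR calling -------------------------------------------------
  params <- do.call(caller_params, cfg$caller %||% list())
  stage_tfcrs <- lapply(stage_hits, function(h) {
    tf <- call_tfcrs(h, params, merge_families = TRUE)
    if (length(tf) >= 10L) tf <- assign_decile_groups(tf)
    tf
  })
  for (st in names(stage_tfcrs)) {
    p <- file.path(cfg$output_dir, sprintf("tfcrs_%s.bed", st))
    write_tfcrs_bed(stage_tfcrs[[st]], p)
    add(p, st)
  }

  # ---- annotation ---------------------------------------------------
  if (isTRUE(cfg$modules$annotate)) {
    for (st in names(stage_tfcrs)) {
      ann <- annotate_tfcrs(stage_tfcrs[[st]], genes)
      p <- file.path(cfg$output_dir, sprintf("annotation_%s.tsv", st))
      utils::write.table(ann, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add(p, st)
    }
  }

  # ---- dynamics -----------------------------------------------------
  if (isTRUE(cfg$modules$dynamics)) {
    if (length(stage_tfcrs) < 2L) {
      stop("dynamics module needs at least 2 stages")
    }
    dyn <- classify_dynamics(stage_tfcrs)
    p <- file.path(cfg$output_dir, "dynamics.tsv")
    utils::write.table(dyn, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(p, "all")
  }

  # ---- evolution ----------------------------------------------------
  if (isTRUE(cfg$modules$evolution)) {
    rows <- list()
    for (st in names(stage_tfcrs)) {
      tf <- stage_tfcrs[[st]]
      k <- round(50 * assembly$size_multiple_n)
      if (length(tf) >= 2L * max(1L, k)) {
        sel <- select_top_bottom(tf, assembly$size_multiple_n)
        rows[[st]] <- data.frame(
          stage = st, n = assembly$size_multiple_n, k = sel$k,
          top_assoc = gene_association_fraction(sel$top, genes),
          bottom_assoc = gene_association_fraction(sel$bottom, genes))
      }
    }
    if (length(rows)) {
      p <- file.path(cfg$output_dir, "evolution.tsv")
      utils::write.table(do.call(rbind, rows), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add(p, "all")
    }
  }

  # ---- RegulatoryScore ----------------------------------------------
  gene_tables <- NULL
  if (isTRUE(cfg$modules$regscore)) {
    if (is.null(stage_expr)) {
      stop("regscore module enabled but no expression input available")
    }
    gene_tables <- list()
    for (si in seq_along(stage_tfcrs)) {
      st <- names(stage_tfcrs)[si]
      gt <- build_gene_table(stage_tfcrs[[si]], genes, stage_expr[[si]])
      gene_tables[[st]] <- gt
      p <- file.path(cfg$output_dir, sprintf("gene_table_%s.tsv", st))
      utils::write.table(gt, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add(p, st)
    }
  }

  # ---- ML -----------------------------------------------------------
  if (isTRUE(cfg$modules$ml)) {
    if (is.null(gene_tables)) {
      stop("ml module requires the regscore module (and expression input)")
    }
    if (is.null(sequence)) stop("ml module requires a genome sequence")
    mlc <- cfg$ml %||% list()
    L_p <- mlc$L_p %||% 4000L
    L_t <- mlc$L_t %||% 11113L
    st <- names(gene_tables)[[1L]]
    rec <- build_feature_records(gene_tables[[st]], genes,
                                 stage_tfcrs[[st]], sequence, L_p, L_t)
    if (nrow(rec) < 10L) stop("too few scored genes for the ml module")
    Xy <- encode_feature_matrix(rec, L_p, L_t)
    sp <- split_dataset(rec, seed = child_seed(cfg$seed, "ml_split"))
    spec <- model_spec(
      mlc$method %||% "gbdt",
      hyperparams = mlc[setdiff(names(mlc), c("L_p", "L_t", "method"))],
      seed = child_seed(cfg$seed, "ml_train"))
    model <- train_regressor(spec, Xy[sp$train_idx, , drop = FALSE],
                             rec$score[sp$train_idx])
    metrics <- evaluate_regressor(model, Xy[sp$test_idx, , drop = FALSE],
                                  rec$score[sp$test_idx])
    p <- file.path(cfg$output_dir, "ml_metrics.json")
    jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = 10)
    add(p, st)
    if (isTRUE(ml_method_registry()$tree_based[
        ml_method_registry()$method == spec$method])) {
      att <- attribute_shap(model, Xy[sp$test_idx, , drop = FALSE])
      imp <- utils::head(att$importance, 50L)
      p <- file.path(cfg$output_dir, "ml_importance.tsv")
      utils::write.table(
        data.frame(feature = names(imp), mean_abs_shap = imp),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      add(p, st)
    }
  }

  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest,
                     file.path(cfg$output_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config error: 'seed' is required")
  if (is.null(cfg$output_dir)) stop("config error: 'output_dir' is required")
  if (is.null(cfg$synth) && is.null(cfg$inputs)) {
    stop("config error: provide either 'synth' or 'inputs'")
  }
  cfg$modules <- utils::modifyList(
    list(annotate = TRUE, dynamics = TRUE, evolution = TRUE,
         regscore = TRUE, ml = FALSE),
    cfg$modules %||% list())
  # fail before any compute when stage inputs cannot satisfy a module
  if (isTRUE(cfg$modules$ml) && is.null(cfg$synth) &&
      is.null(cfg$inputs$expression)) {
    stop("config error: ml module enabled but no expression input")
  }
  if (isTRUE(cfg$modules$regscore) && is.null(cfg$synth) &&
      is.null(cfg$inputs$expression)) {
    stop("config error: regscore module enabled but no expression input")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
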