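## End-to-end orchestration from one declarative YAML config: stages run
## in dependency order, outputs land in `out_dir`, and a reproducibility
## manifest records seeds, input checksums, row counts and cache hits.
## Numeric defaults follow the study settings: 5 optimiser restarts,
## evidence-ratio cutoff 2.7, Ks window 0.05-5, clade-split threshold 5,
## kmax 9, 1000 bootstrap replicates at alpha 0.01, Fisher alpha 0.05.

pipeline_defaults <- function() {
  list(
    families = list(restarts = 5, evidence_ratio = 2.7, foreground = "Mob",
                    root_prior = "stationary"),
    ks_peaks = list(window = c(0.05, 5), threshold = 5, kmax = 9,
                    select = "bic", B = 1000, alpha = 0.01),
    nupt = list(min_identity = 90, min_span = 2000, merge = FALSE),
    enrichment = list(alpha = 0.05)
  )
}

stage_order <- c("families", "ks_peaks", "nupt", "enrichment")

known_keys <- list(
  top = c("seed", "out_dir", "stages"),
  families = c("sim", "tree", "counts", "foreground", "restarts",
               "evidence_ratio", "root_prior", "max_families"),
  ks_peaks = c("sim", "samples", "window", "threshold", "kmax", "select",
               "B", "alpha", "ci_B"),
  nupt = c("sim", "hits", "genome_bp", "plastid_bp", "min_identity",
           "min_span", "merge"),
  enrichment = c("subset", "annotations", "universe", "alpha")
)

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown config key%s in %s: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")))
  }
}

#' Read and validate a pipeline run configuration
#'
#' @param path YAML file with top-level keys `seed`, `out_dir` and
#'   `stages`; unknown keys anywhere are rejected before anything runs.
#' @return The validated config list with stage defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A config list (as from YAML).
#' @export
validate_run_config <- function(cfg) {
  check_keys(cfg, known_keys$top, "top level")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$out_dir)) stop("config needs an out_dir")
  if (is.null(cfg$stages) || !length(cfg$stages)) stop("config lists no stages")
  bad <- setdiff(names(cfg$stages), stage_order)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  defs <- pipeline_defaults()
  for (st in names(cfg$stages)) {
    check_keys(cfg$stages[[st]], known_keys[[st]], paste0("stage ", st))
    cfg$stages[[st]] <- utils::modifyList(defs[[st]], cfg$stages[[st]])
  }
  cfg
}

# md5 over the stage's resolved config, the master seed and the md5s of
# its input files: any change in one of them invalidates the cache
stage_checksum <- function(stage_cfg, seed, input_paths) {
  sums <- if (length(input_paths)) unname(tools::md5sum(input_paths)) else character(0)
  key <- jsonlite::toJSON(list(cfg = stage_cfg, seed = seed, inputs = sums),
                          auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".key")
  writeLines(as.character(key), tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

log_line <- function(stage, msg) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the analysis pipeline from a declarative config
#'
#' Executes the configured stages in dependency order (`families`,
#' `ks_peaks`, `nupt`, `enrichment`), writing per-stage TSV outputs and
#' a JSON manifest (`manifest.json`) into `out_dir`. A stage whose
#' configuration, seed and input checksums match the previous manifest
#' and whose outputs still exist is skipped as a cache hit. A stage
#' failure stops the run with the manifest recording the failure point.
#'
#' @param config Path to a YAML config or a validated config list.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
             error = function(e) NULL)
  } else NULL
  manifest <- list(
    package = as.character(utils::packageVersion("plastburst")),
    r_version = R.version.string,
    seed = cfg$seed,
    started = format(Sys.time()),
    stages = list()
  )
  for (st in intersect(stage_order, names(cfg$stages))) {
    scfg <- cfg$stages[[st]]
    inputs <- as.character(unlist(scfg[intersect(names(scfg),
                                                 c("tree", "counts", "samples",
                                                   "hits", "subset",
                                                   "annotations", "universe"))]))
    inputs <- inputs[file.exists(inputs)]
    csum <- stage_checksum(scfg, cfg$seed, inputs)
    prev_st <- prev$stages[[st]]
    outputs <- stage_outputs(st, out_dir)
    if (!is.null(prev_st) && identical(prev_st$checksum, csum) &&
        all(file.exists(outputs))) {
      log_line(st, "unchanged inputs; cache hit, skipped")
      manifest$stages[[st]] <- list(checksum = csum, status = "cached",
                                    outputs = outputs, cache_hit = TRUE)
      next
    }
    log_line(st, "running")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(run_stage(st, scfg, cfg$seed, out_dir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[st]] <- list(checksum = csum, status = "failed",
                                    error = conditionMessage(res))
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      stop(sprintf("stage %s failed: %s", st, conditionMessage(res)))
    }
    manifest$stages[[st]] <- c(list(checksum = csum, status = "ok",
                                    outputs = outputs, cache_hit = FALSE,
                                    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)),
                               res)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

stage_outputs <- function(st, out_dir) {
  file.path(out_dir, switch(st,
    families = "family_turnover.tsv",
    ks_peaks = c("ks_peaks.tsv", "ks_density.tsv"),
    nupt = c("nupt_summary.tsv", "nupt_links.tsv"),
    enrichment = "enrichment.tsv"))
}

run_stage <- function(st, scfg, seed, out_dir) {
  switch(st,
    families = stage_families(scfg, seed, out_dir),
    ks_peaks = stage_ks_peaks(scfg, seed, out_dir),
    nupt = stage_nupt(scfg, seed, out_dir),
    enrichment = stage_enrichment(scfg, seed, out_dir))
}

stage_families <- function(scfg, seed, out_dir) {
  tree <- if (!is.null(scfg$tree)) parse_newick(file = scfg$tree) else
    species_tree_11()
  if (!is.null(scfg$sim)) {
    sim <- do.call(sim_family_counts,
                   c(list(tree = tree, seed = substream(seed, 1L)), scfg$sim))
    counts <- sim$counts
  } else {
    counts <- read_counts_table(scfg$counts)
  }
  if (!is.null(scfg$max_families)) {
    counts <- counts[seq_len(min(nrow(counts), scfg$max_families)), , drop = FALSE]
  }
  rows <- lapply(rownames(counts), function(fam) {
    cv <- counts[fam, ]
    if (sum(cv) == 0L) return(NULL)
    fg <- fit_turnover(tree, counts[fam, , drop = FALSE], model = "global",
                       n_restarts = scfg$restarts, seed = substream(seed, 2L),
                       root_prior = scfg$root_prior)
    fb <- fit_turnover(tree, counts[fam, , drop = FALSE], model = "branch",
                       foreground = scfg$foreground,
                       n_restarts = scfg$restarts, seed = substream(seed, 3L),
                       root_prior = scfg$root_prior)
    cmp <- compare_models(list(fg, fb), ratio_cutoff = scfg$evidence_ratio)
    cls <- if (cmp$significant && cmp$best_model == "branch") {
      classify_family(fb, tree, cv)
    } else list(call = "stable", lost_all = FALSE,
                reconstructed_parent = NA_integer_)
    data.frame(family = fam, n_genes = sum(cv),
               best_model = cmp$best_model,
               evidence_ratio = cmp$evidence_ratio,
               significant = cmp$significant,
               call = cls$call, lost_all = cls$lost_all,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(out_dir, "family_turnover.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(n_families = nrow(tab),
       n_significant = sum(tab$significant & tab$best_model == "branch"))
}

stage_ks_peaks <- function(scfg, seed, out_dir) {
  if (!is.null(scfg$sim)) {
    sim <- do.call(sim_ks_mixture,
                   c(list(seed = substream(seed, 4L),
                          window = scfg$window), scfg$sim))
    x <- sim$samples; w <- rep(1, length(x))
  } else {
    df <- utils::read.delim(scfg$samples)
    x <- df$ks
    w <- if ("weight" %in% names(df)) df$weight else rep(1, length(x))
  }
  keep <- x >= scfg$window[1L] & x <= scfg$window[2L]
  x <- x[keep]; w <- w[keep]
  fit <- if (identical(scfg$select, "boot")) {
    k <- select_k_bootstrap(x, kmax = scfg$kmax, B = scfg$B,
                            alpha = scfg$alpha, seed = substream(seed, 5L))
    em_fit(x, w, k = k, seed = substream(seed, 6L))
  } else {
    select_k_bic(x, w, kmax = scfg$kmax, seed = substream(seed, 5L))
  }
  ci_B <- if (!is.null(scfg$ci_B)) scfg$ci_B else 200
  peaks <- peak_confidence_intervals(fit, B = ci_B, seed = substream(seed, 7L))
  utils::write.table(cbind(component = seq_len(fit$k), peaks,
                           sd = fit$sigma),
                     file.path(out_dir, "ks_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  grid <- seq(scfg$window[1L], scfg$window[2L], length.out = 512)
  utils::write.table(data.frame(ks = grid,
                                density = gmm_density(grid, fit$lambda,
                                                      fit$mu, fit$sigma)),
                     file.path(out_dir, "ks_density.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(n_samples = length(x), k = fit$k)
}

stage_nupt <- function(scfg, seed, out_dir) {
  if (!is.null(scfg$sim)) {
    sim <- do.call(sim_nupt_genome,
                   c(list(seed = substream(seed, 8L)), scfg$sim))
    hits <- toy_local_align(sim$plastid, sim$nuclear,
                            query_id = "plastid", subject_id = "nuclear")
    genome_bp <- scfg$sim$genome_bp
  } else {
    hits <- read_blast_tab(scfg$hits)
    genome_bp <- scfg$genome_bp
  }
  smry <- summarize_nupt(hits, genome_bp, merge = scfg$merge)
  df <- data.frame(metric = c("n_hits", "n_scaffolds_hit", "total_aligned_bp",
                              "genome_bp", "fraction_pct", "min_len",
                              "max_len", "mean_len", "median_len"),
                   value = c(smry$n_hits, smry$n_scaffolds_hit,
                             smry$total_aligned_bp, smry$genome_bp,
                             100 * smry$fraction, smry$min_len, smry$max_len,
                             smry$mean_len, smry$median_len))
  utils::write.table(df, file.path(out_dir, "nupt_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (smry$n_hits > 0) {
    write_circos_links(color_links(hits), file.path(out_dir, "nupt_links.tsv"))
  } else {
    writeLines(character(0), file.path(out_dir, "nupt_links.tsv"))
  }
  list(n_hits = smry$n_hits, fraction_pct = 100 * smry$fraction)
}

stage_enrichment <- function(scfg, seed, out_dir) {
  ann <- read_annotations(scfg$annotations)
  subset <- readLines(scfg$subset, warn = FALSE)
  subset <- subset[nzchar(subset)]
  universe <- if (!is.null(scfg$universe)) {
    u <- readLines(scfg$universe, warn = FALSE); u[nzchar(u)]
  } else NULL
  res <- enrich_terms(subset, ann, universe = universe, alpha = scfg$alpha)
  utils::write.table(res, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(n_terms = nrow(res), n_significant = sum(res$significant))
}
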