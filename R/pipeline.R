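## End-to-end pipeline driver: stage ordering, TSV/FASTQ artifacts,
## manifests, and a flat YAML configuration.

PIPELINE_STAGES <- c("simulate", "tsignal", "tailcall", "tags", "urid",
                     "coupling", "paltrap", "halflife")

STAGE_DEPS <- list(
  simulate = character(0),
  tsignal = "simulate",
  tailcall = "tsignal",
  tags = "tailcall",
  urid = "tags",
  coupling = "tags",
  paltrap = "simulate",
  halflife = "simulate")

#' Default pipeline configuration
#'
#' @return Named list of configuration defaults (smoke-test scale: 200
#'   genes, 2000 clusters).
#' @export
default_config <- function() {
  list(seed = 1L, protocol = "palseq_v3", stages = PIPELINE_STAGES,
       n_genes = 200L, n_clusters = 2000L, tail_mean = 75, tail_sd = 25,
       tag_sd = 20, coupling_rho = 0.62, paltrap_beta = 0.02,
       urid_rate = 0.05, standard_frac = 0.04, min_tags = 100L,
       dropout_frac = 0.01, expression_depth = 100,
       n_paltrap_tags = 20000L, timecourse_depth = 500, t0 = 0.3,
       train_hmm = FALSE, train_iter = 10L)
}

read_config <- function(config) {
  cfg <- default_config()
  user <- if (is.character(config)) yaml::read_yaml(config)
          else if (is.list(config)) config
          else stop("config must be a path or a list")
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg
}

write_manifest <- function(dir, stage, seed, files) {
  manifest <- list(stage = stage, seed = seed,
                   version = as.character(utils::packageVersion("tailkit")),
                   files = lapply(files, function(f)
                     list(name = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  path <- file.path(dir, paste0(stage, ".manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

write_fastq <- function(ids, seqs, path) {
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order: simulate -> tsignal ->
#' tailcall -> tags -> \{urid, coupling, paltrap, halflife\}. Every stage
#' writes its TSV artifacts plus a JSON manifest (file checksums, stage
#' seed, package version) under `out_dir`; identical configurations produce
#' byte-identical manifests. All randomness derives from the root seed.
#'
#' @param config Path to a YAML configuration or a named list overriding
#'   [default_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("tailkit_")) {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  need <- function(stage, art) {
    if (is.null(art))
      stop("stage '", stage, "' requires missing upstream stage '",
           STAGE_DEPS[[stage]][1], "'", call. = FALSE)
    art
  }
  protocol_hmm <- if (cfg$protocol == "tailseq") "tailseq" else "palseq"
  res <- list()
  manifests <- character(0)
  log_line <- function(...) message("[tailkit] ", ...)

  if ("simulate" %in% stages) {
    seed <- derive_seed(cfg$seed, "simulate")
    config_sim <- sim_config(
      seed = seed, n_genes = cfg$n_genes,
      tail_dist = list(family = "normal", mean = cfg$tail_mean,
                       sd = cfg$tail_sd, tag_sd = cfg$tag_sd),
      coupling_rho = cfg$coupling_rho, paltrap_beta = cfg$paltrap_beta,
      urid_rate = cfg$urid_rate, standard_frac = cfg$standard_frac)
    truth <- simulate_truth(config_sim)
    tags <- simulate_tags(truth, cfg$n_clusters,
                          seed = derive_seed(seed, "tags"))
    model0 <- hmm_init(protocol_hmm)
    cycles <- max(tags$tail_length) + 10L
    clusters <- simulate_clusters(tags, truth, model0, cycles,
                                  seed = derive_seed(seed, "clusters"),
                                  dropout_frac = cfg$dropout_frac)
    expr <- simulate_expression_counts(truth, depth = cfg$expression_depth,
                                       seed = derive_seed(seed, "expr"))
    f_truth <- file.path(out_dir, "truth_genes.tsv")
    write_tsv(truth$genes[setdiff(names(truth$genes), "utr")], f_truth)
    f_tags <- file.path(out_dir, "tags_truth.tsv")
    write_tsv(clusters$tags, f_tags)
    f_expr <- file.path(out_dir, "expression_counts.tsv")
    write_tsv(expr, f_expr)
    f_int <- file.path(out_dir, "intensities.tsv")
    n <- dim(clusters$intensities)[1]; T_ <- dim(clusters$intensities)[2]
    long <- data.frame(cluster_id = rep(clusters$cluster_id, each = T_),
                       cycle = rep(seq_len(T_), times = n))
    for (ch in seq_along(CHANNELS))
      long[[CHANNELS[ch]]] <-
        as.vector(t(clusters$intensities[, , ch]))
    write_tsv(long, f_int)
    f_fq <- file.path(out_dir, "read2.fastq")
    write_fastq(clusters$cluster_id, clusters$read2, f_fq)
    manifests <- c(manifests, write_manifest(
      out_dir, "simulate", seed, c(f_truth, f_tags, f_expr, f_int, f_fq)))
    res$simulate <- list(truth = truth, tags = tags, clusters = clusters,
                         expr = expr, model0 = model0)
    log_line("simulate: ", nrow(tags), " tags, ", cfg$n_genes, " genes")
  }

  if ("tsignal" %in% stages) {
    sim <- need("tsignal", res$simulate)
    seed <- derive_seed(cfg$seed, "tsignal")
    ts <- compute_tsignal(sim$clusters$intensities, sim$clusters$read1_means,
                          sim$clusters$cluster_id)
    ts <- impute_tsignal(ts)
    f_ts <- file.path(out_dir, "tsignal.tsv")
    write_tsv(tsignal_long(ts), f_ts)
    f_dl <- file.path(out_dir, "tsignal_discards.tsv")
    write_tsv(discard_log(ts), f_dl)
    manifests <- c(manifests, write_manifest(out_dir, "tsignal", seed,
                                             c(f_ts, f_dl)))
    res$tsignal <- ts
    log_line("tsignal: ", sum(is.na(ts$discarded)), "/",
             length(ts$discarded), " clusters retained")
  }

  if ("tailcall" %in% stages) {
    ts <- need("tailcall", res$tsignal)
    sim <- need("tailcall", res$simulate)
    seed <- derive_seed(cfg$seed, "tailcall")
    model <- sim$model0
    if (isTRUE(cfg$train_hmm)) {
      keep <- which(is.na(ts$discarded))
      tr_idx <- select_training_set(keep, seed)
      trained <- hmm_train(model,
                           log2(ts$tsignal[tr_idx, , drop = FALSE]),
                           max_iter = cfg$train_iter)
      model <- trained$model
    }
    called <- call_tails(model, ts)
    f_calls <- file.path(out_dir, "tail_calls.tsv")
    write_tsv(called$calls, f_calls)
    manifests <- c(manifests, write_manifest(out_dir, "tailcall", seed,
                                             f_calls))
    res$tailcall <- called
    log_line("tailcall: ", nrow(called$calls), " tails called")
  }

  if ("tags" %in% stages) {
    called <- need("tags", res$tailcall)
    sim <- need("tags", res$simulate)
    seed <- derive_seed(cfg$seed, "tags")
    tag_tab <- merge(sim$clusters$tags, called$calls, by = "cluster_id")
    names(tag_tab)[names(tag_tab) == "tail_length.x"] <- "tail_true"
    names(tag_tab)[names(tag_tab) == "tail_length.y"] <- "tail_length"
    std <- tag_tab[tag_tab$is_standard, ]
    std_counts <- as.matrix(table(std$feature_id, std$sample_id))
    sf <- tryCatch(size_factors(std_counts), error = function(e) NULL)
    summ <- summarize_tails(tag_tab, min_tags = cfg$min_tags,
                            protocol = cfg$protocol)
    f_tab <- file.path(out_dir, "tag_table.tsv")
    write_tsv(tag_tab, f_tab)
    f_med <- file.path(out_dir, "median_tails.tsv")
    write_tsv(summ$medians, f_med)
    f_hist <- file.path(out_dir, "tail_histograms.tsv")
    hists <- do.call(rbind, lapply(names(summ$histograms), function(s) {
      h <- summ$histograms[[s]]$corrected
      data.frame(sample_id = s, tail_length = as.integer(names(h)),
                 count = as.numeric(h),
                 norm_count = if (!is.null(sf) && s %in% names(sf))
                   as.numeric(h) / sf[[s]] else as.numeric(h),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(hists, f_hist)
    manifests <- c(manifests, write_manifest(out_dir, "tags", seed,
                                             c(f_tab, f_med, f_hist)))
    res$tags <- list(table = tag_tab, size_factors = sf, summary = summ)
    log_line("tags: ", nrow(summ$medians), " features with >= ",
             cfg$min_tags, " tags")
  }

  if ("urid" %in% stages) {
    tg <- need("urid", res$tags)
    seed <- derive_seed(cfg$seed, "urid")
    uf <- urid_frequency(tg$table)
    f_uf <- file.path(out_dir, "urid_frequency.tsv")
    write_tsv(uf, f_uf)
    manifests <- c(manifests, write_manifest(out_dir, "urid", seed, f_uf))
    res$urid <- uf
    log_line("urid: ", nrow(uf), " tail-length strata")
  }

  if ("coupling" %in% stages) {
    tg <- need("coupling", res$tags)
    sim <- need("coupling", res$simulate)
    seed <- derive_seed(cfg$seed, "coupling")
    te <- compute_te(setNames(sim$expr$rna, sim$expr$gene_id),
                     setNames(sim$expr$fp, sim$expr$gene_id),
                     sim$expr$cds_len, sim$expr$mito,
                     mode = "median-centered")
    cc <- tryCatch(
      coupling_correlation(tg$summary$medians, te, min_tags = cfg$min_tags),
      error = function(e) list(rs = NA_real_, n = 0L))
    f_te <- file.path(out_dir, "te_table.tsv")
    write_tsv(te, f_te)
    f_cc <- file.path(out_dir, "coupling.tsv")
    write_tsv(data.frame(rs = cc$rs, n = cc$n), f_cc)
    manifests <- c(manifests, write_manifest(out_dir, "coupling", seed,
                                             c(f_te, f_cc)))
    res$coupling <- list(te = te, coupling = cc)
    log_line("coupling: Rs = ", round(cc$rs, 3), " over ", cc$n, " genes")
  }

  if ("paltrap" %in% stages) {
    sim <- need("paltrap", res$simulate)
    seed <- derive_seed(cfg$seed, "paltrap")
    pt <- simulate_paltrap(sim$truth, cfg$n_paltrap_tags,
                           beta = cfg$paltrap_beta, seed = seed)
    st <- paltrap_stats(pt$input, pt$eluate, min_tags = cfg$min_tags)
    f_iso <- file.path(out_dir, "paltrap_isoforms.tsv")
    write_tsv(st$isoforms, f_iso)
    manifests <- c(manifests, write_manifest(out_dir, "paltrap", seed,
                                             f_iso))
    res$paltrap <- st
    log_line("paltrap: ", nrow(st$isoforms), " isoforms, frac(diff>0) = ",
             round(st$frac_longer, 3))
  }

  if ("halflife" %in% stages) {
    sim <- need("halflife", res$simulate)
    seed <- derive_seed(cfg$seed, "halflife")
    tc <- simulate_timecourse(sim$truth, t0 = cfg$t0,
                              depth = cfg$timecourse_depth, seed = seed)
    norm <- normalize_timecourse(tc$labeled, tc$input, tc$times)
    norm <- steady_state_filter(norm)
    fits <- fit_condition(norm)
    f_fit <- file.path(out_dir, "halflife_fits.tsv")
    write_tsv(fits$fits, f_fit)
    manifests <- c(manifests, write_manifest(out_dir, "halflife", seed,
                                             f_fit))
    res$halflife <- fits
    log_line("halflife: t0* = ", fits$t0, ", ",
             sum(fits$fits$converged), " converged fits")
  }

  invisible(list(results = res, manifests = manifests, out_dir = out_dir,
                 config = cfg))
}
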