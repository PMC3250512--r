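#' Run the full biogeographic province analysis
#'
#' Orchestrates: read community matrix and coordinates, Hellinger transform,
#' constrained MRT with multiple cross-validation per longitude encoding
#' scheme, size selection under both rules, province assignment, plus the
#' Raup-Crick similarity matrix and its agglomerative dendrogram. All results
#' are written as delimited text/JSON/newick under `outdir`; a manifest
#' records seeds, parameters and package version so a run can be reproduced
#' exactly (the manifest is the only file carrying a timestamp).
#'
#' @param config a named list or path to a JSON file with fields:
#'   `community` (path to the site-by-species table) or `matrix` (a
#'   [community_matrix()]); `coords` (path) or `sites` (data frame); `outdir`;
#'   optional `schemes` (default `"greenwich_pm180"`), `folds` (10),
#'   `replicates` (1000), `seed` (1), `min_node_size` (2), `sep` (`","`),
#'   `raup_crick_null` (`"equiprobable"`).
#' @return (invisibly) a list with the per-scheme results, the Raup-Crick
#'   matrix, the dendrogram, and the manifest.
#' @export
run_biogeography <- function(config) {
  cfg <- load_config(config)
  defaults <- list(schemes = "greenwich_pm180", folds = 10, replicates = 1000,
                   seed = 1, min_node_size = 2, sep = ",",
                   raup_crick_null = "equiprobable")
  cfg <- modifyList(defaults, cfg)
  for (f in c("community", "coords"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input path does not exist: ", cfg[[f]])
  if (is.null(cfg$outdir)) stop("config must name an output directory")

  mat <- if (!is.null(cfg$matrix)) cfg$matrix
         else read_presence_absence(cfg$community, sep = cfg$sep)
  sites <- if (!is.null(cfg$sites)) validate_site_records(cfg$sites)
           else read_site_coords(cfg$coords, sep = cfg$sep)
  n <- nrow(mat$occurrences)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  degenerate <- n < 3 || cfg$folds > n
  if (degenerate)
    warning(sprintf(
      "cross-validation is undefined for %d site(s) at v = %d; reporting a single province",
      n, cfg$folds))

  resp <- hellinger(mat)
  scheme_results <- list()
  for (sc in cfg$schemes) {
    sdir <- file.path(cfg$outdir, sc)
    dir.create(sdir, showWarnings = FALSE)
    cons <- build_constraints(sites, sc, site_order = mat$site_ids)
    if (degenerate) {
      prov <- stats::setNames(rep(1L, n), mat$site_ids)
      res <- list(size_most_frequent = 1L, size_one_se = 1L, provinces = prov)
      tree_lines <- "root leaf (cross-validation skipped)"
    } else {
      mcv <- multi_cv(resp, cons, replicates = cfg$replicates, v = cfg$folds,
                      seed = cfg$seed, min_node_size = cfg$min_node_size)
      smf <- select_size(mcv, "most_frequent_min")
      sse <- select_size(mcv, "one_se")
      prov <- assign_provinces(mcv$tree, mcv$pruning, smf)
      write.table(mcv$summary, file.path(sdir, "xerror.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(size = as.integer(names(mcv$size_freq)),
                             frequency = as.integer(mcv$size_freq)),
                  file.path(sdir, "size_freq.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      tree_lines <- format_mrt(mcv$tree)
      jsonlite::write_json(
        list(nodes = data.frame(
          id = seq_along(mcv$tree$left), left = mcv$tree$left,
          right = mcv$tree$right,
          split_var = ifelse(mcv$tree$split_var > 0,
                             mcv$tree$var_names[pmax(mcv$tree$split_var, 1)],
                             NA_character_),
          threshold = mcv$tree$threshold, n = mcv$tree$n, ss = mcv$tree$ss)),
        file.path(sdir, "tree.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
      res <- list(multicv = mcv, size_most_frequent = smf, size_one_se = sse,
                  provinces = prov)
    }
    jsonlite::write_json(list(size_most_frequent = res$size_most_frequent,
                              size_one_se = res$size_one_se),
                         file.path(sdir, "selection.json"), auto_unbox = TRUE)
    write.table(data.frame(site_id = names(res$provinces),
                           province = as.integer(res$provinces)),
                file.path(sdir, "provinces.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(tree_lines, file.path(sdir, "tree.txt"))
    scheme_results[[sc]] <- res
  }
  if (length(cfg$schemes) > 1) {
    comp <- data.frame(
      scheme = cfg$schemes,
      size_most_frequent = vapply(scheme_results, `[[`, integer(1),
                                  "size_most_frequent"),
      size_one_se = vapply(scheme_results, `[[`, integer(1), "size_one_se"))
    write.table(comp, file.path(cfg$outdir, "scheme_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  rc <- raup_crick(mat, null = cfg$raup_crick_null, seed = cfg$seed)
  write.table(data.frame(site_id = rownames(rc), unclass(rc)[,],
                         check.names = FALSE),
              file.path(cfg$outdir, "raup_crick.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dend <- NULL
  if (n >= 2) {
    dend <- agglomerate(rc)
    write_newick(dend, file.path(cfg$outdir, "dendrogram.nwk"))
  }

  manifest <- list(
    package = "ventbiogeo",
    version = as.character(utils::packageVersion("ventbiogeo")),
    timestamp = format(Sys.time(), tz = "UTC"),
    parameters = cfg[setdiff(names(cfg), c("matrix", "sites"))])
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(schemes = scheme_results, raup_crick = rc, dendrogram = dend,
                 manifest = manifest))
}

load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  config
}

#' Pairwise TN93 distances and divergence dates for an alignment
#'
#' Computes all pairwise Tamura-Nei distances (percent) for an aligned FASTA
#' file (or `aligned_set` matrix) and dates each divergence at the supplied
#' substitution rate. Saturated pairs are reported per pair, not fatally.
#'
#' @param alignment path to an aligned FASTA file, or an `aligned_set`.
#' @param rate_percent_per_My substitution rate in percent per million years;
#'   see [dating_rate_presets()].
#' @param outdir optional directory; if given, writes `distances.tsv`.
#' @return data frame with one row per sequence pair: ids, `percent`,
#'   `time_My`, `time_My_rounded`, and `note` (`"ok"` or the per-pair error).
#' @export
run_divergence <- function(alignment, rate_percent_per_My = 0.53,
                           outdir = NULL) {
  aln <- if (is.character(alignment) && !is.matrix(alignment))
    read_alignment(alignment) else alignment
  if (nrow(aln) < 2) stop("need at least 2 sequences")
  ids <- rownames(aln)
  pairs <- combn(ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    pr <- pairs[, k]
    est <- tryCatch(tamura_nei(aln, pr), error = function(e) e)
    if (inherits(est, "error"))
      return(data.frame(id1 = pr[1], id2 = pr[2], percent = NA_real_,
                        time_My = NA_real_, time_My_rounded = NA_real_,
                        note = conditionMessage(est)))
    dt <- date_divergence(est$percent, rate_percent_per_My)
    data.frame(id1 = pr[1], id2 = pr[2], percent = est$percent,
               time_My = dt$time_My, time_My_rounded = dt$time_My_rounded,
               note = "ok")
  })
  out <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(out, file.path(outdir, "distances.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
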