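#' Pipeline configuration
#'
#' All tunable parameters of the per-subject pipeline and the group
#' comparison, with defaults matching the reference analysis: 9-34 Hz
#' zero-phase Butterworth band (orders 4/8), embedding dimension 2 at delay
#' 1 sample, 10% edge density, 10 random reference graphs, 5% significance.
#'
#' @param filter a [filter_spec()].
#' @param m,tau embedding dimension and delay (samples).
#' @param density binarization edge density.
#' @param n_rand number of random reference graphs.
#' @param alpha significance / gate level.
#' @param norm distance-norm variant, `"range"` or `"chebyshev"`.
#' @param ecc_summary eccentricity summary, `"mean"` or `"max"`.
#' @param seed base seed for random reference graphs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(filter = filter_spec(), m = 2L, tau = 1L,
                            density = 0.10, n_rand = 10L, alpha = 0.05,
                            norm = "range", ecc_summary = "mean", seed = 1L) {
  structure(list(filter = filter, m = as.integer(m), tau = as.integer(tau),
                 density = as.numeric(density), n_rand = as.integer(n_rand),
                 alpha = as.numeric(alpha), norm = norm,
                 ecc_summary = ecc_summary, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline for one subject
#'
#' Composes the per-subject chain: trim pre-stimulus, average epochs,
#' zero-phase band filtering, rescale, pairwise JDistEn coupling,
#' fixed-density binarization, network metrics with random-reference
#' normalization.
#'
#' @param rec an [epoched_recording()].
#' @param config a [pipeline_config()].
#' @param seed seed for this subject's random reference graphs (defaults to
#'   `config$seed`).
#' @param keep_intermediates also return the coupling matrix and binary
#'   network.
#' @return one-row `data.frame` of metrics (see [network_metrics()]); with
#'   `keep_intermediates`, a list with `metrics`, `coupling`, `network`,
#'   `preprocessed`.
#' @export
run_subject <- function(rec, config = pipeline_config(), seed = config$seed,
                        keep_intermediates = FALSE) {
  pp <- preprocess_subject(rec, config$filter)
  w <- coupling_matrix(pp$data, config$m, config$tau, config$norm)
  bn <- binarize_fixed_density(w, config$density)
  metrics <- network_metrics(bn, config$n_rand, seed, config$ecc_summary)
  if (keep_intermediates) {
    list(metrics = metrics, coupling = w, network = bn, preprocessed = pp)
  } else {
    metrics
  }
}

#' Run the pipeline over a cohort and compare groups
#'
#' Applies [run_subject()] to every subject (each with a private
#' random-reference seed derived from `config$seed`; simulations over many
#' cohorts should give each cohort its own `config$seed` so reference draws
#' stay independent across cohorts), assembles the
#' per-subject metrics table, and compares the two groups on each network
#' metric with the normality-gated test. A subject whose pipeline fails
#' (degenerate channel, undefined metric) is skipped with a record rather
#' than aborting the cohort. Outliers are screened per metric and group by
#' both Chauvenet's criterion and the IQR rule; they are reported, not
#' removed.
#'
#' @param subjects list of subjects as from [generate_cohort()]: each a
#'   list with `rec`, `group` and optionally `id`.
#' @param config a [pipeline_config()].
#' @return list with `metrics` (per-subject data.frame), `comparisons`
#'   (per-metric data.frame: group means/SDs, test used, statistic, p,
#'   significance), `outliers` (per metric and group), `skipped`.
#' @export
run_cohort <- function(subjects, config = pipeline_config()) {
  groups <- vapply(subjects, `[[`, "", "group")
  if (any(table(groups) < 3) || length(unique(groups)) != 2) {
    jdnet_stop("jdnet_bad_config", "need two groups with >= 3 subjects each")
  }
  ids <- vapply(seq_along(subjects), function(i) {
    if (!is.null(subjects[[i]]$id)) subjects[[i]]$id else sprintf("S%02d", i)
  }, "")
  seeds <- config$seed + 7919L * seq_along(subjects)   # disjoint reference streams
  rows <- vector("list", length(subjects))
  skipped <- character(0)
  for (i in seq_along(subjects)) {
    rows[[i]] <- tryCatch(
      cbind(data.frame(id = ids[i], group = groups[i]),
            run_subject(subjects[[i]]$rec, config, seed = seeds[i])),
      jdnet_error = function(e) {
        skipped <<- c(skipped, sprintf("%s: %s", ids[i], conditionMessage(e)))
        NULL
      })
  }
  metrics <- do.call(rbind, rows)
  metric_names <- c("clustering", "path_length", "eccentricity", "q")
  comp <- lapply(metric_names, function(mn) {
    a <- metrics[[mn]][metrics$group == "A"]
    b <- metrics[[mn]][metrics$group == "B"]
    cg <- compare_groups(a, b, config$alpha)
    data.frame(metric = mn, mean_a = cg$mean_a, sd_a = cg$sd_a,
               mean_b = cg$mean_b, sd_b = cg$sd_b, test = cg$test,
               statistic = cg$statistic, p = cg$p,
               significant = cg$significant)
  })
  outliers <- lapply(stats::setNames(metric_names, metric_names), function(mn) {
    lapply(stats::setNames(c("A", "B"), c("A", "B")), function(g) {
      v <- metrics[[mn]][metrics$group == g]
      if (length(v) < 4) {
        list(chauvenet = integer(0), iqr = integer(0))   # screens need n >= 4
      } else {
        list(chauvenet = chauvenet_outliers(v), iqr = iqr_outliers(v))
      }
    })
  })
  list(metrics = metrics, comparisons = do.call(rbind, comp),
       outliers = outliers, skipped = skipped)
}

#' Write / read a pipeline configuration
#'
#' Serializes a [pipeline_config()] (including its [filter_spec()]) to a
#' key-value JSON file at full numeric precision, so a stored configuration
#' reproduces a run exactly. `read_pipeline_config()` restores an
#' identical object.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$filter <- unclass(x$filter)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(filter = do.call(filter_spec, y$filter),
                  m = y$m, tau = y$tau, density = y$density,
                  n_rand = y$n_rand, alpha = y$alpha, norm = y$norm,
                  ecc_summary = y$ecc_summary, seed = y$seed)
}
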