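# Plate-level aggregation and statistics.
#
# Percent NETosis per well = 100 x NET-forming cells / total
# Hoechst-positive cells, pooling fields within the well; border objects
# are excluded before counting. Wells (not fields) are the replicate unit
# for the statistics: unpaired t test for two groups, one-way ANOVA for
# more, significance stars at p < 0.05 / 0.01 / 0.001, no
# multiple-testing correction (p-values are reported unadjusted).

#' Summarize one well's cell classes
#'
#' @param records per-object data.frame for the well (border objects
#'   should already be excluded).
#' @param classes character vector of classes aligned with `records` rows
#'   (two- or four-channel vocabulary).
#' @param well_id well identifier.
#' @param treatment treatment label carried into the summary.
#' @return one-row data.frame; with `n_total = 0` all percentages are
#'   `NA` and `undefined` is `TRUE`.
#' @export
summarize_well <- function(records, classes, well_id, treatment = "") {
  stopifnot(nrow(records) == length(classes))
  four <- any(classes %in% FOUR_CHANNEL_CLASSES)
  n_total <- length(classes)
  cnt <- function(cl) sum(classes == cl)
  pct <- function(k) if (n_total > 0) 100 * k / n_total else NA_real_
  n_net <- cnt("TYPE1_NET") + cnt("NET")
  if (four) {
    n_necrotic <- cnt("NECROTIC")
    n_apoptotic <- cnt("APOPTOTIC")
    n_other <- n_necrotic + n_apoptotic
    n_live <- cnt("LIVE")
  } else {
    n_necrotic <- NA_integer_
    n_apoptotic <- NA_integer_
    n_other <- cnt("TYPE2_OTHER_DEATH")
    n_live <- cnt("TYPE3_LIVE")
  }
  data.frame(
    well_id = well_id,
    treatment = treatment,
    n_total = n_total,
    n_net = n_net,
    n_other_death = n_other,
    n_necrotic = n_necrotic,
    n_apoptotic = n_apoptotic,
    n_live = n_live,
    pct_net = pct(n_net),
    pct_other_death = pct(n_other),
    pct_live = pct(n_live),
    fields_used = length(unique(records$field_index)),
    undefined = n_total == 0,
    stringsAsFactors = FALSE
  )
}

#' Dose- or time-response table
#'
#' @param summaries data.frame of well summaries ([summarize_well] rows);
#'   for `axis = "TIME"` a `time_point_min` column must be present.
#' @param layout a [plate_layout] supplying each well's concentration
#'   (`axis = "CONCENTRATION"`).
#' @param axis `"CONCENTRATION"` or `"TIME"`.
#' @return data.frame ordered by ascending axis value with per-class mean
#'   percentages, SEM (sample SD / sqrt(n wells), `NA` for n = 1) and the
#'   number of replicate wells.
#' @export
build_response_table <- function(summaries, layout,
                                 axis = c("CONCENTRATION", "TIME")) {
  axis <- match.arg(axis)
  if (axis == "CONCENTRATION") {
    m <- match(summaries$well_id, layout$wells$well_id)
    if (anyNA(m)) {
      ns_stop(
        paste("wells missing from layout:",
              paste(summaries$well_id[is.na(m)], collapse = ", ")),
        "netscan_config_error"
      )
    }
    summaries$axis_value <- layout$wells$concentration[m]
  } else {
    if (is.null(summaries$time_point_min)) {
      ns_stop("TIME axis requires a time_point_min column",
              "netscan_config_error")
    }
    summaries$axis_value <- summaries$time_point_min
  }
  sem <- function(x) {
    if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  }
  agg <- function(col) {
    means <- tapply(summaries[[col]], summaries$axis_value, mean)
    sems <- tapply(summaries[[col]], summaries$axis_value, sem)
    list(mean = means, sem = sems)
  }
  net <- agg("pct_net"); other <- agg("pct_other_death")
  live <- agg("pct_live")
  vals <- as.numeric(names(net$mean))
  out <- data.frame(
    axis_value = vals,
    mean_pct_net = as.numeric(net$mean),
    sem_pct_net = as.numeric(net$sem),
    mean_pct_other_death = as.numeric(other$mean),
    sem_pct_other_death = as.numeric(other$sem),
    mean_pct_live = as.numeric(live$mean),
    sem_pct_live = as.numeric(live$sem),
    n_wells = as.integer(table(summaries$axis_value)),
    stringsAsFactors = FALSE
  )
  out[order(out$axis_value), , drop = FALSE]
}

#' @noRd
significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "ns"
}

#' Compare per-well percentages between treatment groups
#'
#' Two groups: unpaired two-sample t test (equal variance by default,
#' Welch via `welch = TRUE`). Three or more: one-way ANOVA F test.
#'
#' @param group_values named list of numeric vectors (per-well values,
#'   e.g. `pct_net`), each of length >= 2.
#' @param welch use the Welch t test instead of the pooled-variance test.
#' @return a `group_comparison` list: per-group mean and SEM, test name,
#'   statistic, degrees of freedom, `p_value` and significance `stars`.
#' @export
compare_groups <- function(group_values, welch = FALSE) {
  if (length(group_values) < 2L) {
    ns_stop("need at least two groups", "netscan_param_error")
  }
  ns <- vapply(group_values, length, integer(1))
  if (any(ns < 2L)) {
    ns_stop("every group needs >= 2 replicate wells",
            "netscan_replicates_error")
  }
  means <- vapply(group_values, mean, numeric(1))
  sems <- vapply(group_values, function(x) stats::sd(x) / sqrt(length(x)),
                 numeric(1))
  if (length(group_values) == 2L) {
    test <- "UNPAIRED_T"
    ht <- tryCatch(
      stats::t.test(group_values[[1]], group_values[[2]],
                    var.equal = !welch),
      error = function(e) NULL  # degenerate: both groups constant
    )
    if (is.null(ht)) {
      df <- sum(ns) - 2
      if (isTRUE(all.equal(means[[1]], means[[2]]))) {
        statistic <- 0; p <- 1
      } else {
        statistic <- sign(means[[1]] - means[[2]]) * Inf; p <- 0
      }
    } else {
      statistic <- unname(ht$statistic)
      df <- unname(ht$parameter)
      p <- ht$p.value
    }
  } else {
    test <- "ONE_WAY_ANOVA"
    vals <- unlist(group_values, use.names = FALSE)
    grp <- factor(rep(seq_along(group_values), ns))
    ht <- tryCatch(stats::oneway.test(vals ~ grp, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ht)) {
      df <- c(length(ns) - 1, sum(ns) - length(ns))
      if (stats::var(means) == 0) { statistic <- 0; p <- 1 }
      else { statistic <- Inf; p <- 0 }
    } else {
      statistic <- unname(ht$statistic)
      df <- unname(ht$parameter)
      p <- ht$p.value
    }
  }
  # identical groups give sd 0 and an undefined statistic; report p = 1
  if (is.nan(statistic)) { statistic <- 0; p <- 1 }
  structure(
    list(
      group_means = means,
      group_sems = sems,
      n_per_group = ns,
      test = test,
      statistic = statistic,
      df = df,
      p_value = p,
      stars = significance_stars(p)
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: statistic = %.4g, p = %.4g (%s)\n",
    x$test, x$statistic, x$p_value, x$stars
  ))
  for (i in seq_along(x$group_means)) {
    nm <- names(x$group_means)[i] %||% as.character(i)
    cat(sprintf("  group %s: mean %.3f +/- SEM %.3f (n = %d)\n",
                nm, x$group_means[i], x$group_sems[i], x$n_per_group[i]))
  }
  invisible(x)
}
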