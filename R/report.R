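## Study report: summary tables (mean ± SEM), fold changes, predictive
## correlations, group comparisons and time-course figures.

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

## Long-format summary of one metric column by group x session.
summarise_metric <- function(metrics, col, tracer = NULL) {
  rows <- if (is.null(tracer)) metrics[metrics$tracer == "CT", , drop = FALSE]
          else metrics[metrics$tracer == tracer, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  agg <- split(rows[[col]], list(rows$group, rows$session), drop = TRUE)
  keys <- do.call(rbind, strsplit(names(agg), ".", fixed = TRUE))
  data.frame(metric = if (is.null(tracer)) col else paste(tracer, col, sep = "_"),
             group = keys[, 1], session = as.integer(keys[, 2]),
             mean = vapply(agg, function(v) mean(v[is.finite(v)]), 0),
             sem = vapply(agg, sem, 0),
             n = vapply(agg, function(v) sum(is.finite(v)), 0L),
             row.names = NULL)
}

## Per-animal value of a metric at one session (NA when the scan is
## missing); animals taken from the metrics table.
metric_by_animal <- function(metrics, col, tracer, session, group = NULL) {
  rows <- metrics[metrics$tracer == tracer & metrics$session == session, , drop = FALSE]
  if (!is.null(group)) rows <- rows[rows$group == group, , drop = FALSE]
  stats::setNames(rows[[col]], rows$animal_id)
}

#' Fold-change table at established fibrosis
#'
#' Group-mean ratios at the final session: bleomycin vehicle vs control
#' for mean lung density (HU + 1000 scale), FDG and FMISO lung %ID/g,
#' and vehicle vs each treated arm for the same three read-outs.
#'
#' @param metrics Per-scan metrics from [quantify_study()] /
#'   [quantify_session()].
#' @param session Nominal session day (default 23).
#' @return Data frame with `contrast`, `readout`, `fold_change`.
#' @export
fold_change_table <- function(metrics, session = 23) {
  grab <- function(group, tracer, col)
    metric_by_animal(metrics, col, tracer, session, group)
  readouts <- list(
    MLD = list(tracer = "CT", col = "mld_hu", scale = "hu1000"),
    FDG_idg = list(tracer = "FDG", col = "lung_idg", scale = "linear"),
    FMISO_idg = list(tracer = "FMISO", col = "lung_idg", scale = "linear"))
  contrasts <- list(
    `BLM/NaCl` = c("BLM", "NaCl"),
    `BLM/BLM+pirfenidone` = c("BLM", "BLM+pirfenidone"),
    `BLM/BLM+nintedanib` = c("BLM", "BLM+nintedanib"))
  out <- list()
  for (cn in names(contrasts)) for (rn in names(readouts)) {
    r <- readouts[[rn]]
    a <- grab(contrasts[[cn]][1], r$tracer, r$col)
    b <- grab(contrasts[[cn]][2], r$tracer, r$col)
    fc <- if (sum(is.finite(a)) && sum(is.finite(b)))
      group_fold_change(a[is.finite(a)], b[is.finite(b)], r$scale) else NA_real_
    out[[length(out) + 1L]] <- data.frame(contrast = cn, readout = rn,
                                          fold_change = fc)
  }
  do.call(rbind, out)
}

#' Early-marker correlation table
#'
#' For each bleomycin arm: Pearson correlation of day-9 mean lung
#' density, day-9 FDG lung %ID/g and day-9 FMISO lung %ID/g with the
#' progression score delta-CT (day 9 to 23).
#'
#' @param metrics Per-scan metrics table.
#' @param start_day,end_day Progression-score window (defaults 9 and 23).
#' @return Data frame with `group`, `marker`, `r`, `p`, `n`.
#' @export
correlation_table <- function(metrics, start_day = 9, end_day = 23) {
  ct <- metrics[metrics$tracer == "CT", , drop = FALSE]
  groups <- intersect(c("BLM", "BLM+pirfenidone", "BLM+nintedanib"),
                      unique(metrics$group))
  out <- list()
  for (g in groups) {
    ids <- unique(ct$animal_id[ct$group == g])
    dct <- vapply(ids, function(id) {
      tl <- ct[ct$animal_id == id, c("day", "mld_hu")]
      tryCatch(delta_ct(tl, start_day, end_day, animal_id = id)$delta_ct_hu,
               error = function(e) NA_real_)
    }, 0)
    markers <- list(
      MLD_D9 = metric_by_animal(metrics, "mld_hu", "CT", start_day, g),
      FDG_D9 = metric_by_animal(metrics, "lung_idg", "FDG", start_day, g),
      FMISO_D9 = metric_by_animal(metrics, "lung_idg", "FMISO", start_day, g))
    for (mn in names(markers)) {
      x <- markers[[mn]][ids]
      res <- tryCatch(predictive_correlation(x, dct),
                      error = function(e) list(r = NA_real_, p = NA_real_,
                                               n = sum(is.finite(x) & is.finite(dct))))
      out[[length(out) + 1L]] <- data.frame(group = g, marker = mn,
                                            r = res$r, p = res$p, n = res$n)
    }
  }
  do.call(rbind, out)
}

#' Build the study report
#'
#' Writes the per-scan metrics, the group summary (mean ± SEM), the
#' fold-change and correlation tables, per-session group comparisons
#' and time-course figures. Missing scans are flagged (not silently
#' dropped): the returned `warnings` counts empty study cells.
#'
#' @param metrics Per-scan metrics table.
#' @param out_dir Output directory.
#' @return List with the tables and `warnings` (count of missing study
#'   cells), invisibly.
#' @export
build_report <- function(metrics, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary_tbl <- rbind(
    summarise_metric(metrics, "mld_hu"),
    summarise_metric(metrics, "aerated_pct"),
    summarise_metric(metrics, "lung_idg", "FDG"),
    summarise_metric(metrics, "lung_idg", "FMISO"),
    summarise_metric(metrics, "ltbr", "FDG"),
    summarise_metric(metrics, "ltbr", "FMISO"),
    if ("mlv_pct" %in% names(metrics)) summarise_metric(metrics, "mlv_pct", "FDG"),
    summarise_metric(metrics, "hlv_pct", "FMISO"))
  summary_tbl <- summary_tbl[order(summary_tbl$metric, summary_tbl$group,
                                   summary_tbl$session), ]
  fc <- fold_change_table(metrics)
  corr <- correlation_table(metrics)

  ## per-session group comparisons of the three main read-outs
  cmp <- list()
  for (ses in setdiff(sort(unique(metrics$session)), 0)) {
    for (spec in list(c("CT", "mld_hu"), c("FDG", "lung_idg"),
                      c("FMISO", "lung_idg"))) {
      rows <- metrics[metrics$tracer == spec[1] & metrics$session == ses, , drop = FALSE]
      groups <- split(rows[[spec[2]]], rows$group)
      groups <- lapply(groups, function(v) v[is.finite(v)])
      groups <- groups[lengths(groups) > 0]
      if (length(groups) < 2) next
      res <- compare_groups(groups)
      cmp[[length(cmp) + 1L]] <- data.frame(
        session = ses, readout = paste(spec, collapse = "_"),
        method = res$method, p = res$p, stars = res$stars)
    }
  }
  cmp <- if (length(cmp)) do.call(rbind, cmp) else NULL

  ## completeness: every (group, session, modality) cell should be filled
  expected <- expand.grid(group = unique(metrics$group), session = SESSION_DAYS,
                          tracer = c("CT", TRACERS), stringsAsFactors = FALSE)
  have <- unique(metrics[, c("group", "session", "tracer")])
  filled <- paste(expected$group, expected$session, expected$tracer) %in%
    paste(have$group, have$session, have$tracer)
  n_missing <- sum(!filled)
  if (n_missing > 0)
    warning(n_missing, " study cell(s) have no scans; report is partial")

  write.csv(metrics, file.path(out_dir, "per_scan_metrics.csv"), row.names = FALSE)
  write.csv(summary_tbl, file.path(out_dir, "group_summary.csv"), row.names = FALSE)
  write.csv(fc, file.path(out_dir, "fold_changes.csv"), row.names = FALSE)
  write.csv(corr, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  if (!is.null(cmp))
    write.csv(cmp, file.path(out_dir, "group_comparisons.csv"), row.names = FALSE)
  plot_time_courses(summary_tbl, out_dir)
  invisible(list(summary = summary_tbl, fold_changes = fc, correlations = corr,
                 comparisons = cmp, warnings = n_missing))
}

## Time-course figures (mean ± SEM per group) for the headline metrics.
plot_time_courses <- function(summary_tbl, out_dir) {
  panels <- c(mld_hu = "Mean lung density (HU)",
              aerated_pct = "Aerated lung (%)",
              FDG_lung_idg = "FDG lung uptake (%ID/g)",
              FMISO_lung_idg = "FMISO lung uptake (%ID/g)")
  for (m in names(panels)) {
    d <- summary_tbl[summary_tbl$metric == m & is.finite(summary_tbl$mean), ]
    if (!nrow(d)) next
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$session, y = .data$mean,
                                         colour = .data$group)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             width = 0.4) +
      ggplot2::labs(x = "Study day", y = panels[[m]], colour = NULL) +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(out_dir, paste0("timecourse_", m, ".png")),
                    p, width = 5, height = 3.5, dpi = 150)
  }
  invisible(NULL)
}
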