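#' Flagged fraction indices of a GDSA series
#'
#' @param results data.frame from [analyzeSeries()] (needs columns
#'   \code{fraction} and \code{gdsa_mean_pct}).
#' @param thresholdPct flag threshold on |GDSA_mu|, percent (default 3);
#'   the comparison is inclusive.
#'
#' @return Integer vector of flagged fraction indices, in fraction order.
#' @export
flagSeries <- function(results, thresholdPct = 3) {
  stopifnot(is.data.frame(results),
            all(c("fraction", "gdsa_mean_pct") %in% names(results)))
  results <- results[order(results$fraction), ]
  results$fraction[abs(results$gdsa_mean_pct) >= thresholdPct]
}

#' Coefficient of determination of y regressed on x
#'
#' Ordinary least-squares R-squared of the line of \code{y} on \code{x}:
#' \code{1 - SSE/SST}.
#'
#' @param x,y paired numeric vectors, at least 3 complete pairs; \code{x}
#'   must not be constant.
#'
#' @return Scalar in [0, 1].
#' @export
rSquared <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 paired points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate regression: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}

#' Per-site cohort summary of a GDSA analysis
#'
#' Aggregates pooled per-fraction GDSA results by treatment site: number
#' of patients, number of fractions, share of the cohort's fractions
#' (percent, one decimal), number of fractions with |GDSA_mu| at or above
#' the flag threshold, and the mean and standard deviation (population
#' form) of GDSA_mu.
#'
#' @param results pooled data.frame of [analyzeSeries()] rows across
#'   patients (columns \code{patient_id}, \code{site}, \code{fraction},
#'   \code{gdsa_mean_pct}, \code{flagged}).
#'
#' @return data.frame with columns \code{site}, \code{patients},
#'   \code{fractions}, \code{pct_total}, \code{flagged},
#'   \code{mean_gdsa_pct}, \code{sd_gdsa_pct}, ordered by descending
#'   fraction count.
#' @export
cohortSummary <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("patient_id", "site", "gdsa_mean_pct", "flagged") %in%
                  names(results)))
  total <- nrow(results)
  rows <- lapply(split(results, results$site), function(d) {
    data.frame(site = d$site[1L],
               patients = length(unique(d$patient_id)),
               fractions = nrow(d),
               pct_total = round(100 * nrow(d) / total, 1L),
               flagged = sum(d$flagged),
               mean_gdsa_pct = mean(d$gdsa_mean_pct),
               sd_gdsa_pct = sqrt(mean((d$gdsa_mean_pct -
                                          mean(d$gdsa_mean_pct))^2)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fractions, out$site), ]
  rownames(out) <- NULL
  out
}

#' Read a per-site cohort table
#'
#' Reads a CSV with columns \code{site}, \code{patients},
#' \code{fractions}, \code{flagged} (one row per treatment site) and adds
#' the cohort share of each site's fractions in percent (one decimal).
#' The package ships an example head-and-neck VMAT cohort table under
#' \code{system.file("extdata", "hn_cohort_sites.csv", package =
#' "epidGDSA")}.
#'
#' @param path CSV path.
#'
#' @return data.frame with the four input columns plus \code{pct_total}.
#' @export
readCohortTable <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "patients", "fractions", "flagged")
  if (!all(need %in% names(out)))
    stop("cohort table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out$pct_total <- round(100 * out$fractions / sum(out$fractions), 1L)
  out
}

#' Export per-patient GDSA time series as plots and a tidy CSV
#'
#' Writes one plot per patient of GDSA_mu versus fraction number with
#' error bars of one ROI standard deviation, horizontal lines at the
#' positive and negative flag threshold, flagged fractions drawn in red,
#' and the series split at each re-baseline fraction. When separation or
#' rotation records are supplied, the effective separation change
#' diameter (or the pitch angle) is overlaid on a secondary axis. All
#' plotted values go to \code{timeseries.csv} in the same directory.
#'
#' @param results data.frame from [analyzeSeries()] (possibly several
#'   patients pooled).
#' @param separations optional data.frame from [analyzeSeparations()]
#'   with a \code{patient_id} column (or for a single patient, without).
#' @param rotations optional data.frame from [analyzeRotations()],
#'   likewise.
#' @param dir output directory (created if missing).
#' @param thresholdPct flag threshold drawn on the plots (default 3).
#'
#' @return Character vector of written file paths, invisibly.
#' @export
exportTimeseries <- function(results, separations = NULL, rotations = NULL,
                             dir, thresholdPct = 3) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tidy <- results
  tidy <- .mergeAux(tidy, separations,
                    c("delta_dap_cm", "delta_dlat_cm", "delta_deff_cm"))
  tidy <- .mergeAux(tidy, rotations, c("pitch_deg", "roll_deg", "yaw_deg"))
  csv <- file.path(dir, "timeseries.csv")
  utils::write.csv(tidy, csv, row.names = FALSE, na = "")
  paths <- csv
  for (pid in unique(tidy$patient_id)) {
    d <- tidy[tidy$patient_id == pid, ]
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$fraction,
                                         y = .data$gdsa_mean_pct)) +
      ggplot2::geom_hline(yintercept = c(-thresholdPct, thresholdPct),
                          linetype = "dashed", colour = "grey40") +
      ggplot2::geom_line(ggplot2::aes(group = .data$reference_fraction)) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$gdsa_mean_pct - .data$gdsa_std_pct,
                     ymax = .data$gdsa_mean_pct + .data$gdsa_std_pct),
        width = 0.3, colour = "grey55") +
      ggplot2::geom_point(ggplot2::aes(colour = .data$flagged),
                          size = 2, show.legend = FALSE) +
      ggplot2::scale_colour_manual(
        values = c(`FALSE` = "black", `TRUE` = "red")) +
      ggplot2::labs(x = "fraction number",
                    y = expression(GDSA[mu] ~ "(%)"),
                    title = pid)
    if (!is.null(separations) && "delta_deff_cm" %in% names(d) &&
        any(is.finite(d$delta_deff_cm))) {
      sc <- max(abs(d$gdsa_mean_pct), thresholdPct) /
        max(d$delta_deff_cm, 1)
      p <- p +
        ggplot2::geom_line(ggplot2::aes(y = .data$delta_deff_cm * sc),
                           colour = "steelblue", linetype = "dotdash",
                           na.rm = TRUE) +
        ggplot2::scale_y_continuous(
          sec.axis = ggplot2::sec_axis(~ . / sc,
                                       name = "effective separation change (cm)"))
    } else if (!is.null(rotations) && "pitch_deg" %in% names(d) &&
               any(is.finite(d$pitch_deg))) {
      sc <- max(abs(d$gdsa_mean_pct), thresholdPct) /
        max(abs(d$pitch_deg), 1)
      p <- p +
        ggplot2::geom_line(ggplot2::aes(y = .data$pitch_deg * sc),
                           colour = "steelblue", linetype = "dotdash",
                           na.rm = TRUE) +
        ggplot2::scale_y_continuous(
          sec.axis = ggplot2::sec_axis(~ . / sc, name = "pitch (deg)"))
    }
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", pid),
                               "_gdsa.png"))
    suppressMessages(ggplot2::ggsave(f, p, width = 7, height = 4, dpi = 120))
    paths <- c(paths, f)
  }
  invisible(paths)
}

.mergeAux <- function(tidy, aux, cols) {
  if (is.null(aux)) return(tidy)
  keep <- intersect(c("patient_id", "fraction", cols), names(aux))
  by <- intersect(c("patient_id", "fraction"), keep)
  merge(tidy, aux[, keep, drop = FALSE], by = by, all.x = TRUE,
        sort = TRUE)
}

#' @importFrom rlang .data
NULL
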