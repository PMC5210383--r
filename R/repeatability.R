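#' Bland-Altman agreement analysis of paired session measurements
#'
#' For paired measurements (session 1, session 2) of the same quantity:
#' differences `d = s1 - s2`, bias = mean(d), `sd_diff` = SD(d), limits of
#' agreement `bias -/+ 1.96 sd_diff`, coefficient of variation
#' `CV = 100 * sd_diff / grand_mean` (grand mean over all 2n measurements),
#' and minimal detectable difference `MDD = 1.96 * sd_diff`.
#'
#' @param session1,session2 numeric vectors of paired measurements (cm).
#'   Incomplete pairs (NA in either session) are dropped with a warning.
#' @return An object of class `repeatability_result` with fields `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `cv` (percent), `mdd`, `grand_mean`,
#'   `n_pairs`, and `plot_data` (data.frame of pair means and differences).
#' @export
bland_altman <- function(session1, session2) {
  if (length(session1) != length(session2))
    stop("session vectors must have equal length")
  complete <- is.finite(session1) & is.finite(session2)
  if (any(!complete)) {
    warning(sum(!complete), " incomplete pair(s) excluded")
    session1 <- session1[complete]
    session2 <- session2[complete]
  }
  n <- length(session1)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- session1 - session2
  m <- (session1 + session2) / 2
  bias <- mean(d)
  sd_diff <- sd(d)
  grand_mean <- mean(c(session1, session2))
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 cv = 100 * sd_diff / grand_mean,
                 mdd = 1.96 * sd_diff,
                 grand_mean = grand_mean, n_pairs = n,
                 plot_data = data.frame(mean = m, difference = d)),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(paste0("<repeatability_result> n = %d pairs\n",
                     "  bias %.3f, LoA [%.3f, %.3f]\n",
                     "  CV %.2f%%, MDD %.3f\n"),
              x$n_pairs, x$bias, x$loa_low, x$loa_high, x$cv, x$mdd))
  invisible(x)
}

#' @export
plot.repeatability_result <- function(x, ...) {
  pd <- x$plot_data
  graphics::plot(pd$mean, pd$difference,
                 xlab = "Pair mean", ylab = "Difference (session 1 - 2)", ...)
  graphics::abline(h = x$bias, lty = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 1)
  invisible(x)
}

#' Repeatability summary table per muscle and condition
#'
#' Expects tidy long-format data with one row per subject x muscle x
#' condition x session, e.g. the CSV written by the fascicle-length pipeline.
#' For each muscle x condition cell it reports Mean +/- SD of the
#' per-subject session-mean values (between-subject SD), the CV and the MDD
#' from [bland_altman()] on the session pairs.
#'
#' @param data data.frame with columns `muscle`, `condition`, `subject`,
#'   `session` (1 or 2), `value`.
#' @return data.frame with columns `muscle`, `condition`, `mean`, `sd`
#'   (between-subject; NA with a single subject), `cv`, `mdd`, `n_pairs`.
#' @export
repeatability_table <- function(data) {
  need <- c("muscle", "condition", "subject", "session", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  cells <- unique(data[, c("muscle", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- data[data$muscle == cells$muscle[i] &
                  data$condition == cells$condition[i], ]
    wide <- merge(sub[sub$session == 1, c("subject", "value")],
                  sub[sub$session == 2, c("subject", "value")],
                  by = "subject", suffixes = c("_1", "_2"))
    if (nrow(wide) == 0L) {
      warning("no complete session pairs for muscle ", cells$muscle[i],
              ", condition ", cells$condition[i], "; row omitted")
      return(NULL)
    }
    subj_means <- rowMeans(wide[, c("value_1", "value_2")])
    ba <- if (nrow(wide) >= 2L) bland_altman(wide$value_1, wide$value_2) else NULL
    data.frame(muscle = cells$muscle[i], condition = cells$condition[i],
               mean = mean(subj_means),
               sd = if (length(subj_means) > 1L) sd(subj_means) else NA_real_,
               cv = if (is.null(ba)) NA_real_ else ba$cv,
               mdd = if (is.null(ba)) NA_real_ else ba$mdd,
               n_pairs = nrow(wide))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
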