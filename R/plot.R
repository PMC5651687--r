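#' Plot the weight trajectory of a run
#'
#' One line per tracked pair, weight against block (epoch) index.
#'
#' @param x An `eq_run` with a non-empty trajectory.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.eq_run <- function(x, ...) {
  if (!nrow(x$trajectory)) stop("run tracked no pairs", call. = FALSE)
  graphics::matplot(x$trajectory, type = "l", lty = 1, lwd = 2,
                    xlab = "block / epoch", ylab = "connection value",
                    ylim = c(min(0, min(x$trajectory)), 1), ...)
  graphics::legend("topleft", legend = colnames(x$trajectory),
                   col = seq_len(ncol(x$trajectory)), lty = 1, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Bar chart of a nodal-distance relatedness profile
#'
#' @param profile A data frame from [nodal_profile()] (or the `profile`
#'   element of an `eq_replication`).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_nodal_profile <- function(profile, ...) {
  graphics::barplot(profile$mean_weight,
                    names.arg = profile$category,
                    ylab = "mean relatedness", ylim = c(0, 1), ...)
  invisible(profile)
}
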