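#' Plot a candidate-region scan: association track over the Ho track
#'
#' A minimal two-track display: -log10(p) per SNP on top (with the
#' significance cutoff, if given) and the raw plus smoothed Ho index below.
#' Requires ggplot2 (suggested).
#'
#' @param profile Ho profile, ideally after [smoothHo()]
#' @param assoc optional matching [assocScan()] result
#' @param sigThreshold optional -log10(p) cutoff to draw
#' @return a ggplot object
#' @export
plotHoScan <- function(profile, assoc = NULL, sigThreshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotHoScan requires the ggplot2 package")
  tracks <- data.frame(pos = profile$pos, value = profile$ho,
                       track = "Ho index")
  if (!is.null(assoc))
    tracks <- rbind(tracks,
                    data.frame(pos = assoc$pos, value = assoc$neglog10p,
                               track = "-log10(p)"))
  pos <- value <- y <- NULL  # NSE bindings
  p <- ggplot2::ggplot(tracks, ggplot2::aes(x = pos, y = value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(track ~ ., scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_bw()
  if ("ho_smoothed" %in% names(profile)) {
    sm <- profile[!is.na(profile$ho_smoothed), ]
    if (nrow(sm))
      p <- p + ggplot2::geom_line(
        data = data.frame(pos = sm$smoothed_pos, value = sm$ho_smoothed,
                          track = "Ho index"),
        colour = "red")
  }
  if (!is.null(sigThreshold) && !is.null(assoc))
    p <- p + ggplot2::geom_hline(
      data = data.frame(track = "-log10(p)", y = sigThreshold),
      ggplot2::aes(yintercept = y), linetype = "dashed")
  p
}
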