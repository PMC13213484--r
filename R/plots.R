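#' Fingerprint heatmap
#'
#' Heatmap of Z-score fingerprints, one row per profile, features on the
#' x-axis in region order (cell, cytoplasm, nuclei): decreased features in
#' blue, increased in red. The first profile in `fingerprints` is drawn on
#' top, so passing the reference fingerprint first reproduces the usual
#' reference-on-top layout.
#'
#' @param fingerprints Named list of [fingerprint] objects on one feature
#'   set.
#' @param cap Absolute Z at which the colour scale saturates.
#' @return A ggplot object.
#' @export
plot_fingerprint_heatmap <- function(fingerprints, cap = 10) {
  stopifnot(length(fingerprints) >= 1L)
  labs <- names(fingerprints) %||%
    vapply(fingerprints, function(f) paste0(f$compound, "@",
                                            f$concentration_uM),
           character(1L))
  df <- do.call(rbind, Map(function(nm, f) {
    data.frame(profile = nm, feature = seq_along(f$z),
               z = pmax(pmin(unname(f$z), cap), -cap),
               stringsAsFactors = FALSE)
  }, labs, fingerprints))
  df$profile <- factor(df$profile, levels = rev(labs))
  ggplot2::ggplot(df, ggplot2::aes(x = feature, y = profile,
                                   fill = z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-cap, cap),
                                  name = "Z") +
    ggplot2::labs(x = "feature (cell | cytoplasm | nuclei)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Line plot of a single fingerprint
#'
#' Per-feature Z-scores in feature order, with the change threshold drawn
#' as horizontal guides — the view used to read off the most strongly
#' varied individual parameters.
#'
#' @param fp A [fingerprint].
#' @param min_abs Guide lines at +/- this Z.
#' @return A ggplot object.
#' @export
plot_fingerprint_line <- function(fp, min_abs = 10) {
  stopifnot(inherits(fp, "fingerprint"))
  df <- data.frame(feature = seq_along(fp$z), z = unname(fp$z))
  ggplot2::ggplot(df, ggplot2::aes(x = feature, y = z)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(-min_abs, min_abs),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "feature", y = "Z-score",
                  title = paste0(fp$compound, " @ ", fp$concentration_uM,
                                 " uM")) +
    ggplot2::theme_minimal()
}

#' Cross-biosimilarity heatmap
#'
#' @param m A `biosimilarity_matrix`.
#' @return A ggplot object with percent labels in each tile.
#' @export
plot_biosimilarity_matrix <- function(m) {
  df <- expand.grid(a = rownames(m), b = colnames(m),
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(unclass(m))
  ggplot2::ggplot(df, ggplot2::aes(x = b, y = a,
                                   fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", value)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#D56988", high = "#3D729D",
                                 limits = c(0, 100),
                                 name = "biosimilarity (%)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
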