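#' Set-by-phenotype enrichment summary figure
#'
#' Draws the result table as a dot grid: phenotypes on the x-axis, sets on
#' the y-axis, dot fill encoding the normalized enrichment score on a
#' diverging scale centered at NES = 1 (the null expectation), and a ring —
#' red by default — around every cell whose adjusted p-value falls below the
#' significance level. The figure's backing data are exactly the rows of the
#' result table (no aggregation), so the ring count equals the number of
#' significant rows.
#'
#' @param result A `csea_result` from [csea()]; must be nonempty.
#' @param sig_level Significance level; defaults to the one in the result's
#'   configuration.
#' @param color_by `"nes"` (default) or `"es"` for the fill scale.
#' @param output_path Optional path; extension `.png`/`.svg`/`.pdf` writes a
#'   static image, `.html` writes a self-contained page embedding the figure
#'   and, in a `<script type="application/json">` block, the backing data.
#' @param width,height Device size in inches for static export.
#' @param ring_color Color of the significance ring.
#' @return The ggplot object, invisibly when writing a file.
#' @importFrom rlang .data
#' @export
plot_enrichment <- function(result, sig_level = NULL, color_by = c("nes", "es"),
                            output_path = NULL, width = 7, height = 5,
                            ring_color = "red") {
  if (!inherits(result, "csea_result") || nrow(result) == 0)
    csea_stop("`result` must be a nonempty csea_result",
              "csea_nothing_to_plot_error")
  color_by <- match.arg(color_by)
  cfg <- attr(result, "config")
  if (is.null(sig_level)) sig_level <- if (!is.null(cfg)) cfg$sig_level else 0.05
  df <- as.data.frame(result)
  df$significant_at_level <- df$p_adjusted < sig_level
  df$phenotype_id <- factor(df$phenotype_id, levels = unique(df$phenotype_id))
  df$set_id <- factor(df$set_id, levels = rev(sort(unique(df$set_id))))
  midpoint <- if (color_by == "nes") 1 else stats::median(df$es)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype_id,
                                        y = .data$set_id)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data[[color_by]]),
                        shape = 21, size = 6, color = "grey35",
                        stroke = 0.3) +
    ggplot2::geom_point(data = df[df$significant_at_level, , drop = FALSE],
                        shape = 21, size = 8, stroke = 1.2,
                        color = ring_color, fill = NA) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = midpoint,
                                  name = toupper(color_by)) +
    ggplot2::labs(x = "phenotype", y = "set",
                  caption = sprintf("ring: adjusted p < %g", sig_level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (is.null(output_path)) return(p)
  ext <- tolower(sub(".*\\.", "", output_path))
  if (ext %in% c("png", "svg", "pdf")) {
    ggplot2::ggsave(output_path, p, width = width, height = height,
                    dpi = 150)
  } else if (ext %in% c("html", "htm")) {
    tmp <- tempfile(fileext = ".png")
    ggplot2::ggsave(tmp, p, width = width, height = height, dpi = 150)
    on.exit(unlink(tmp))
    b64 <- jsonlite::base64_enc(readBin(tmp, "raw", file.info(tmp)$size))
    backing <- jsonlite::toJSON(df, dataframe = "rows", digits = NA)
    writeLines(c(
      "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
      "<title>Custom set enrichment</title></head><body>",
      "<h3>Custom set enrichment</h3>",
      sprintf("<img alt=\"enrichment grid\" src=\"data:image/png;base64,%s\">",
              gsub("\\s", "", b64)),
      "<script type=\"application/json\" id=\"enrichment-data\">",
      as.character(backing),
      "</script>",
      "</body></html>"), output_path, useBytes = TRUE)
  } else {
    csea_stop(sprintf("unsupported figure extension '.%s'", ext),
              "csea_io_error")
  }
  invisible(p)
}
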