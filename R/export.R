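## SHELX HKLF4 output and merging statistics.

#' Write indexed reflections as a SHELX HKLF4 file
#'
#' Fixed format `3I4, 2F8.2` (32 characters per line), terminated by the
#' all-zero record. `sigma = sqrt(I)` on the unscaled intensity (the
#' counting-statistics rule for integrated electron counts), then both I and
#' sigma are multiplied by the scale. Auto-scaling picks the largest power
#' of ten `<= 1` such that the maximum scaled intensity fits the column
#' (<= 99999.99). After scaling, sigma is floored at 0.01 so SHELX never
#' sees a non-positive sigma.
#'
#' @param indexed [index_reflections()] output.
#' @param path output path.
#' @param intensity_mode `"max"` (per-spot maximum, default) or `"3d"`
#'   (3D-integrated).
#' @param scale `"auto"` or a positive number.
#' @param include_saturated include reflections whose strongest member was
#'   saturated (default FALSE: their intensities are unreliable).
#' @param include_rejected include reflections that failed the indexing
#'   threshold (default FALSE).
#' @return invisibly, the scale actually applied.
#' @export
write_hklf4 <- function(indexed, path, intensity_mode = c("max", "3d"),
                        scale = "auto", include_saturated = FALSE,
                        include_rejected = FALSE) {
  intensity_mode <- match.arg(intensity_mode)
  df <- as.data.frame(indexed)
  if (!include_rejected && "accepted" %in% names(df))
    df <- df[df$accepted, , drop = FALSE]
  if (!include_saturated && "saturated" %in% names(df))
    df <- df[!df$saturated, , drop = FALSE]
  if (nrow(df) > 0 && max(abs(c(df$h, df$k, df$l))) > 999)
    stop("index magnitude > 999 does not fit HKLF4 columns")
  I <- if (nrow(df) == 0) numeric(0) else
    if (intensity_mode == "max") df$I_max else df$I_3d
  sig <- sqrt(pmax(I, 0))
  if (identical(scale, "auto")) {
    mx <- if (length(I)) max(abs(I), na.rm = TRUE) else 0
    scale <- 1
    while (mx * scale > 99999.99) scale <- scale / 10
  }
  stopifnot(is.numeric(scale), scale > 0)
  Is <- I * scale
  sigs <- pmax(sig * scale, 0.01)
  lines <- character(0)
  if (nrow(df) > 0)
    lines <- sprintf("%4d%4d%4d%8.2f%8.2f", df$h, df$k, df$l, Is, sigs)
  lines <- c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0))
  writeLines(lines, path)
  invisible(scale)
}

#' Read an HKLF4 file
#'
#' @param path HKLF4 file; the terminating all-zero record is dropped.
#' @return data.frame with `h, k, l, I, sigma`.
#' @export
read_hklf4 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parse_num <- function(from, to) as.numeric(substr(lines, from, to))
  out <- data.frame(h = as.integer(parse_num(1, 4)),
                    k = as.integer(parse_num(5, 8)),
                    l = as.integer(parse_num(9, 12)),
                    I = parse_num(13, 20), sigma = parse_num(21, 28))
  zero <- out$h == 0 & out$k == 0 & out$l == 0
  out[!zero, , drop = FALSE]
}

#' Merging residual over Friedel pairs
#'
#' Groups accepted reflections by hkl up to Friedel symmetry
#' (hkl ~ -h-k-l); over every group with at least two members,
#' `R_int = sum |I - <I>_group| / sum I`.
#'
#' @param indexed [index_reflections()] output.
#' @param intensity_mode `"max"` or `"3d"`.
#' @return R_int (NA when no group has two members).
#' @export
friedel_rint <- function(indexed, intensity_mode = c("max", "3d")) {
  intensity_mode <- match.arg(intensity_mode)
  df <- as.data.frame(indexed)
  if ("accepted" %in% names(df)) df <- df[df$accepted, , drop = FALSE]
  I <- if (intensity_mode == "max") df$I_max else df$I_3d
  if (is.null(I)) I <- df$I
  fwd <- paste(df$h, df$k, df$l)
  rev <- paste(-df$h, -df$k, -df$l)
  key <- ifelse(fwd < rev, fwd, rev)
  tab <- table(key)
  multi <- names(tab)[tab >= 2]
  if (length(multi) == 0) return(NA_real_)
  sel <- key %in% multi
  Ig <- I[sel]; kg <- key[sel]
  mean_g <- stats::ave(Ig, kg, FUN = mean)
  sum(abs(Ig - mean_g)) / sum(Ig)
}

#' Write the indexed reflection table as TSV
#'
#' Columns mirror the program's reflection listing: fractional indices,
#' rounded indices, intensity, d spacing, frame of the intensity maximum and
#' detector coordinates, plus the `accepted` flag.
#'
#' @param indexed [index_reflections()] output.
#' @param path output path.
#' @param intensity_mode `"max"` or `"3d"`.
#' @export
write_reflection_table <- function(indexed, path,
                                   intensity_mode = c("max", "3d")) {
  intensity_mode <- match.arg(intensity_mode)
  df <- as.data.frame(indexed)
  out <- data.frame(h_frac = df$h_frac, k_frac = df$k_frac,
                    l_frac = df$l_frac, h = df$h, k = df$k, l = df$l,
                    I = if (intensity_mode == "max") df$I_max else df$I_3d,
                    d = df$d, frame = df$frame_of_max, x = df$x, y = df$y,
                    accepted = df$accepted)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a reflection table written by [write_reflection_table()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_reflection_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
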