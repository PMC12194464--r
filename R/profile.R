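# 1D scattering profiles: calibrated (q, intensity, sigma) with sample
# metadata. Collections of profiles are plain lists; [profiles_to_df()] /
# [df_to_profiles()] bridge to the flat CSV schema.

PROFILE_META_FIELDS <- c("subject_id", "group", "lobe", "pos_row", "pos_col")

#' 1D intensity profile
#'
#' A calibrated scattering profile: strictly increasing q (inverse nm),
#' intensity, and a 1-sigma uncertainty per point, plus sample metadata
#' (subject, experimental group, prostate lobe, grid position). Intensity and
#' sigma may contain non-finite values (e.g. empty integration bins) until
#' [remove_nan()] is applied.
#'
#' @param q strictly increasing numeric vector, inverse nm.
#' @param intensity numeric vector, same length.
#' @param sigma numeric vector of 1-sigma uncertainties, same length,
#'   non-negative where finite. Defaults to `NA`.
#' @param n_pixels optional integer vector: pixels per bin when the profile
#'   came from azimuthal integration.
#' @param meta named list of metadata; `subject_id`, `group`, `lobe`,
#'   `pos_row`, `pos_col` are filled with `NA` when absent, extra fields
#'   (e.g. `sacrifice_day`) are kept.
#' @return an object of class `profile1d`.
#' @export
profile1d <- function(q, intensity, sigma = NULL, n_pixels = NULL,
                      meta = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  n <- length(q)
  if (!n) stop("empty profile", call. = FALSE)
  if (length(intensity) != n) stop("q/intensity length mismatch", call. = FALSE)
  if (any(!is.finite(q))) stop("q must be finite", call. = FALSE)
  if (n > 1 && any(diff(q) <= 0))
    stop("q must be strictly increasing", call. = FALSE)
  sigma <- if (is.null(sigma)) rep(NA_real_, n) else as.numeric(sigma)
  if (length(sigma) != n) stop("sigma length mismatch", call. = FALSE)
  if (any(sigma < 0, na.rm = TRUE))
    stop("sigma must be non-negative", call. = FALSE)
  if (!is.null(n_pixels)) {
    n_pixels <- as.integer(n_pixels)
    if (length(n_pixels) != n) stop("n_pixels length mismatch", call. = FALSE)
  }
  for (f in PROFILE_META_FIELDS) if (is.null(meta[[f]])) meta[[f]] <- NA
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 n_pixels = n_pixels, meta = meta),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> %d points, q in [%.4g, %.4g] nm^-1", length(x$q),
              min(x$q), max(x$q)))
  m <- x$meta
  tags <- c(m$subject_id, m$group, m$lobe)
  tags <- tags[!is.na(tags)]
  if (length(tags)) cat(" [", paste(tags, collapse = "/"), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.profile1d <- function(x, ...) {
  df <- data.frame(q_nm_inv = x$q, intensity = x$intensity, sigma = x$sigma)
  if (!is.null(x$n_pixels)) df$n_pixels <- x$n_pixels
  df
}

#' Flatten a list of profiles to the long CSV schema
#'
#' Columns: subject_id, group, lobe, pos_row, pos_col, q_nm_inv, intensity,
#' sigma (one row per q point).
#'
#' @param profiles list of [profile1d()] objects.
#' @return a `data.frame` in long format.
#' @export
profiles_to_df <- function(profiles) {
  stopifnot(length(profiles) > 0)
  parts <- lapply(profiles, function(p) {
    m <- p$meta
    data.frame(subject_id = as.character(m$subject_id %||% NA),
               group = as.character(m$group %||% NA),
               lobe = as.character(m$lobe %||% NA),
               pos_row = as.integer(m$pos_row %||% NA),
               pos_col = as.integer(m$pos_col %||% NA),
               q_nm_inv = p$q, intensity = p$intensity, sigma = p$sigma)
  })
  do.call(rbind, parts)
}

#' Rebuild profiles from the long CSV schema
#'
#' Inverse of [profiles_to_df()]: rows are grouped by
#' (subject_id, group, lobe, pos_row, pos_col), each group becoming one
#' profile with q sorted ascending as stored.
#'
#' @param df a data.frame with the long-schema columns.
#' @return a list of [profile1d()] objects.
#' @export
df_to_profiles <- function(df) {
  needed <- c("subject_id", "group", "lobe", "pos_row", "pos_col",
              "q_nm_inv", "intensity", "sigma")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  key <- paste(df$subject_id, df$group, df$lobe, df$pos_row, df$pos_col,
               sep = "\r")
  lapply(split(df, key), function(d) {
    profile1d(d$q_nm_inv, d$intensity, d$sigma,
              meta = list(subject_id = as.character(d$subject_id[1]),
                          group = as.character(d$group[1]),
                          lobe = as.character(d$lobe[1]),
                          pos_row = d$pos_row[1], pos_col = d$pos_col[1]))
  })
}
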