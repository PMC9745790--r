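# Camera-trap data preparation.
#
# Raw photographs become analysis-ready counts in three steps: consecutive
# photographs of the same species at the same camera are thinned to
# independent events (>= 30 min apart), events are pooled into multi-day
# sampling occasions anchored at each camera's activation date, and cameras
# within the same grid cell are stacked as spatial replicates of that site.

#' Site-by-occasion count matrix
#'
#' Container for the detection-count matrix consumed by the model fitters.
#' Columns are ordered replicate-major (`rep1_occ1 .. rep1_occT, rep2_occ1,
#' ...`): all occasions of spatial replicate 1, then replicate 2, and so on.
#' Missing cells (`NA`) mean "not surveyed" -- a camera that was absent or
#' inactive -- and are distinct from zero, which means surveyed with no
#' detections.
#'
#' @param counts integer matrix, sites in rows; `NA` for missing cells.
#' @param n_occasions number of temporal sampling occasions per replicate.
#' @param site_ids site identifiers; default taken from `rownames(counts)`.
#' @param partial optional logical matrix flagging cells whose occasion
#'   window only partly overlapped the camera's active period.
#' @param layout `"replicate"` or `"flat"`; how the columns were produced.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, n_occasions, site_ids = rownames(counts),
                         partial = NULL, layout = "replicate") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(counts)))
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count matrix must have at least one site and one column")
  if (ncol(counts) %% n_occasions != 0L)
    stop("number of columns (", ncol(counts),
         ") is not a multiple of n_occasions (", n_occasions, ")")
  vals <- counts[!is.na(counts)]
  if (any(vals < 0L)) stop("counts must be non-negative")
  n_rep <- ncol(counts) %/% n_occasions
  rownames(counts) <- site_ids
  colnames(counts) <- paste0("rep", rep(seq_len(n_rep), each = n_occasions),
                             "_occ", rep(seq_len(n_occasions), n_rep))
  structure(list(counts = counts, n_occasions = as.integer(n_occasions),
                 n_replicates = n_rep, site_ids = site_ids,
                 partial = partial, layout = layout),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "sites x", x$n_replicates,
      "replicate(s) x", x$n_occasions, "occasions (layout:", x$layout, ")\n")
  n_obs <- sum(!is.na(x$counts))
  cat("  ", n_obs, "observed cells,", sum(is.na(x$counts)), "missing;",
      "total count", sum(x$counts, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
as.matrix.count_matrix <- function(x, ...) x$counts

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Site covariate table
#'
#' A data frame of numeric site-level covariates keyed by `site_id`, with
#' attributes recording whether columns have been Z-standardized and, if so,
#' the original centers and scales (needed to back-transform response
#' curves to natural units).
#'
#' @param df data frame whose first column is `site_id`.
#' @param standardized logical flag.
#' @param center,scale named numeric vectors of original means / SDs.
#' @export
site_covariates <- function(df, standardized = FALSE, center = NULL,
                            scale = NULL) {
  if (!"site_id" %in% names(df)) stop("covariate table needs a site_id column")
  df <- as.data.frame(df)
  num <- setdiff(names(df), "site_id")
  if (!all(vapply(df[num], is.numeric, logical(1))))
    stop("all covariate columns must be numeric")
  if (anyNA(df[num])) stop("covariate table contains missing values")
  structure(df, standardized = standardized, center = center, scale = scale,
            class = c("site_covariates", "data.frame"))
}

is_standardized <- function(covs) isTRUE(attr(covs, "standardized"))

covariate_names <- function(covs) setdiff(names(covs), "site_id")

# --- photographic independence filter --------------------------------------

parse_timestamps <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(ts) & !is.na(x))
  if (length(bad))
    stop("unparseable ", what, " in record(s) ",
         paste(head(bad, 5), collapse = ", "), ": '", x[bad[1]], "'")
  ts
}

#' Thin photographs to independent events
#'
#' Within each camera-by-species stream, keeps a photograph only if it falls
#' at least `min_gap_minutes` after the previously *retained* photograph
#' (not merely the previous photograph), so every pair of retained events in
#' a stream is at least the gap apart.  The first photograph of a stream is
#' always retained, and a gap of exactly the threshold counts as
#' independent.  Filtering is idempotent.
#'
#' @param events data frame with columns `camera_id`, `timestamp`
#'   (ISO-8601 text or POSIXct) and `species`.
#' @param min_gap_minutes minimum separation, default 30.
#' @return the retained events, ordered by camera, species and time.
#' @export
filter_independent_events <- function(events, min_gap_minutes = 30) {
  stopifnot(min_gap_minutes > 0)
  need <- c("camera_id", "timestamp", "species")
  if (!all(need %in% names(events)))
    stop("events need columns: ", paste(need, collapse = ", "))
  events$timestamp <- parse_timestamps(events$timestamp)
  events <- events[order(events$camera_id, events$species, events$timestamp), ,
                   drop = FALSE]
  keep <- logical(nrow(events))
  groups <- split(seq_len(nrow(events)),
                  list(events$camera_id, events$species), drop = TRUE)
  gap <- min_gap_minutes * 60
  for (idx in groups) {
    last <- -Inf
    for (i in idx) {
      t_i <- as.numeric(events$timestamp[i])
      if (t_i - last >= gap) {
        keep[i] <- TRUE
        last <- t_i
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- occasion pooling ------------------------------------------------------

#' Pool one camera's events into sampling occasions
#'
#' Bins independent events into consecutive occasions of
#' `occasion_length_days` days each, anchored at the camera's own activation
#' date (deployments were staggered, so the occasion calendar is per
#' camera).  Occasion `t` covers days `[(t-1)*L, t*L)` after activation.
#' Occasions wholly outside the active period are missing (`NA`); occasions
#' the camera was active for only part of are counted but flagged as
#' partial, and can instead be dropped with `include_partial = FALSE`.
#'
#' @param events independence-filtered events of one camera (and typically
#'   one species); events at other cameras are ignored with a warning.
#' @param deployment one-row data frame with `camera_id`, `site_id`,
#'   `active_start`, `active_end` (dates) and optionally `trap_nights`.
#' @param occasion_length_days days per occasion, default 3.
#' @param n_occasions number of occasions, default 15.
#' @param include_partial keep counts from partially active occasions
#'   (flagged) rather than setting them missing.
#' @return list with `counts` (length `n_occasions`, `NA` = not surveyed),
#'   `partial` (logical flags), `camera_id`, `site_id`.
#' @export
pool_occasions <- function(events, deployment, occasion_length_days = 3,
                           n_occasions = 15, include_partial = TRUE) {
  stopifnot(occasion_length_days >= 1, n_occasions >= 1,
            nrow(deployment) == 1)
  L <- occasion_length_days
  start <- as.Date(deployment$active_start)
  end <- as.Date(deployment$active_end)
  n_days <- as.integer(end - start) + 1L
  if (n_days < 1L) stop("deployment of ", deployment$camera_id,
                        " has active_end before active_start")

  counts <- integer(n_occasions)
  occ_start <- (seq_len(n_occasions) - 1L) * L
  occ_end <- occ_start + L                      # exclusive
  partial <- occ_start < n_days & occ_end > n_days
  inactive <- occ_start >= n_days
  counts[inactive] <- NA_integer_
  if (!include_partial) counts[partial] <- NA_integer_

  if (nrow(events)) {
    other <- events$camera_id != deployment$camera_id
    if (any(other)) {
      warning(sum(other), " event(s) at other cameras ignored")
      events <- events[!other, , drop = FALSE]
    }
  }
  if (nrow(events)) {
    ts <- parse_timestamps(events$timestamp)
    day <- floor(as.numeric(difftime(ts, as.POSIXct(paste(start, "00:00:00"),
                                                    tz = "UTC"),
                                     units = "days")))
    outside <- day < 0 | day >= n_days
    if (any(outside)) {
      warning(sum(outside), " event(s) outside the active period of ",
              deployment$camera_id, " excluded")
      day <- day[!outside]
    }
    occ <- day %/% L + 1L
    occ <- occ[occ <= n_occasions]
    tab <- tabulate(occ, nbins = n_occasions)
    counts[!is.na(counts)] <- counts[!is.na(counts)] + tab[!is.na(counts)]
  }
  list(counts = counts, partial = partial,
       camera_id = as.character(deployment$camera_id),
       site_id = as.character(deployment$site_id))
}

#' Stack per-camera occasion rows into a site-level count matrix
#'
#' Cameras within one site are spatial replicates: the site's row holds each
#' camera's occasion history in its own replicate-major block of columns.
#' Every site gets the site-wide maximum number of replicate blocks; sites
#' with fewer cameras carry missing cells in the surplus blocks.  Replicate
#' order within a site follows the sorted camera identifiers.
#'
#' @param rows list of [pool_occasions()] results, one per camera.
#' @param max_replicates optional fixed number of replicate blocks; default
#'   is the largest number of cameras at any site (warning above 4, the
#'   design maximum).
#' @return a [count_matrix()].
#' @export
aggregate_to_sites <- function(rows, max_replicates = NULL) {
  if (!length(rows)) stop("no camera rows supplied")
  site_of <- vapply(rows, `[[`, character(1), "site_id")
  cam_of <- vapply(rows, `[[`, character(1), "camera_id")
  if (anyNA(site_of) || any(site_of == ""))
    stop("camera(s) with unknown site: ",
         paste(cam_of[is.na(site_of) | site_of == ""], collapse = ", "))
  n_occ <- length(rows[[1]]$counts)
  sites <- sort(unique(site_of))
  per_site <- table(site_of)
  if (is.null(max_replicates)) max_replicates <- max(per_site)
  if (max(per_site) > 4)
    warning("site(s) with more than 4 cameras: ",
            paste(names(per_site)[per_site > 4], collapse = ", "))
  if (max(per_site) > max_replicates)
    stop("a site has more cameras than max_replicates")

  m <- matrix(NA_integer_, length(sites), max_replicates * n_occ,
              dimnames = list(sites, NULL))
  part <- matrix(FALSE, length(sites), max_replicates * n_occ,
                 dimnames = list(sites, NULL))
  for (s in seq_along(sites)) {
    idx <- which(site_of == sites[s])
    idx <- idx[order(cam_of[idx])]
    for (k in seq_along(idx)) {
      cols <- (k - 1L) * n_occ + seq_len(n_occ)
      m[s, cols] <- rows[[idx[k]]]$counts
      part[s, cols] <- rows[[idx[k]]]$partial
    }
  }
  count_matrix(m, n_occasions = n_occ, partial = part, layout = "replicate")
}

#' Photographic capture-rate index
#'
#' Independent photographs per unit effort (trap-nights), the simple
#' encounter index used to summarize camera-level activity such as human
#' disturbance.
#'
#' @param n_photos non-negative count of independent photographs.
#' @param trap_nights positive number of camera-active days.
#' @export
capture_rate <- function(n_photos, trap_nights) {
  if (any(n_photos < 0)) stop("n_photos must be non-negative")
  if (any(trap_nights <= 0)) stop("capture rate undefined for zero effort")
  n_photos / trap_nights
}

# --- covariate QC ----------------------------------------------------------

#' Z-standardize site covariates
#'
#' Centers and scales every covariate column to mean 0, SD 1 (sample SD,
#' denominator n-1).  The original means and SDs are stored so response
#' curves can be mapped back to natural units.
#'
#' @param covs a [site_covariates()] table (or data frame with `site_id`).
#' @return standardized [site_covariates()] with `center`/`scale` attributes.
#' @export
standardize_covariates <- function(covs) {
  if (!inherits(covs, "site_covariates")) covs <- site_covariates(covs)
  if (is_standardized(covs)) return(covs)
  num <- covariate_names(covs)
  ctr <- vapply(covs[num], mean, numeric(1))
  scl <- vapply(covs[num], sd, numeric(1))
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero))
    stop("zero-variance covariate(s): ", paste(num[zero], collapse = ", "))
  for (v in num) covs[[v]] <- (covs[[v]] - ctr[[v]]) / scl[[v]]
  site_covariates(covs, standardized = TRUE, center = ctr, scale = scl)
}

#' Undo Z-standardization
#'
#' @param covs a standardized [site_covariates()] table.
#' @export
unstandardize_covariates <- function(covs) {
  if (!is_standardized(covs)) return(covs)
  ctr <- attr(covs, "center"); scl <- attr(covs, "scale")
  for (v in covariate_names(covs)) covs[[v]] <- covs[[v]] * scl[[v]] + ctr[[v]]
  site_covariates(covs, standardized = FALSE)
}

#' Flag strongly correlated covariate pairs
#'
#' Computes pairwise Pearson correlations and returns every unordered pair
#' with `|r|` at or above the threshold (default 0.7).  Model construction
#' refuses formulas that place a flagged pair together.
#'
#' @param covs a [site_covariates()] table.
#' @param threshold absolute-correlation cutoff in (0, 1].
#' @return data frame with columns `var1`, `var2`, `r` (possibly 0 rows).
#' @export
collinearity_screen <- function(covs, threshold = 0.7) {
  stopifnot(threshold > 0, threshold <= 1)
  num <- covariate_names(covs)
  if (nrow(covs) < 3) stop("need at least 3 sites to screen correlations")
  if (length(num) < 2)
    return(data.frame(var1 = character(), var2 = character(), r = numeric()))
  cm <- cor(as.matrix(covs[num]))
  idx <- which(abs(cm) >= threshold & upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(var1 = num[idx[, 1]], var2 = num[idx[, 2]],
                    r = cm[idx], stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}
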