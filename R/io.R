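# CSV readers and writers.
#
# All files are plain UTF-8 CSV with "NA" as the single missing-value
# sentinel.  The count-matrix reader accepts two layouts: the package's
# replicate-major layout (columns rep<k>_occ<t>) and a flat site-by-occasion
# layout (any other set of numeric columns, one per occasion), auto-detected
# from the header and reported.

#' Read a site-by-occasion count matrix
#'
#' The first column must be the site identifier.  Headers matching
#' `rep<k>_occ<t>` are read as the replicate-major layout; any other header
#' is treated as the flat one-column-per-occasion layout (single replicate,
#' as when cameras were pre-pooled per site).  The detected layout is
#' reported with a message and recorded in the result.
#'
#' @param path CSV file.
#' @param quiet suppress the layout message.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, quiet = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count CSV needs a site id column plus data columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[-1])
  bad <- which(!is.na(m) & (m < 0 | m != round(m)), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at row ", bad[1, 1], ", column '",
         colnames(m)[bad[1, 2]], "'")
  rep_major <- all(grepl("^rep[0-9]+_occ[0-9]+$", colnames(m)))
  if (rep_major) {
    occ <- as.integer(sub("^rep[0-9]+_occ", "", colnames(m)))
    n_occ <- max(occ)
    layout <- "replicate"
  } else {
    n_occ <- ncol(m)
    layout <- "flat"
  }
  if (!quiet)
    message("read_count_matrix: detected ", layout, " layout (",
            ncol(m) / n_occ, " replicate(s) x ", n_occ, " occasions)")
  rownames(m) <- ids
  count_matrix(m, n_occasions = n_occ, layout = layout)
}

#' Write a count matrix to CSV
#' @param counts a [count_matrix()].
#' @param path output file.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(site_id = counts$site_ids,
                   as.data.frame(counts$counts, check.names = FALSE),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a site-covariate table
#'
#' The first column must be `site_id`; remaining columns are numeric
#' covariates.  If every column already has mean ~0 and SD ~1 the table is
#' flagged as pre-standardized and left untouched; otherwise it is
#' Z-standardized (original means/SDs retained).  If a count matrix is
#' supplied, site identifiers must match it one-to-one.
#'
#' @param path CSV file.
#' @param counts optional [count_matrix()] to validate site ids against.
#' @param tol tolerance for declaring a column pre-standardized.
#' @return a standardized [site_covariates()] table.
#' @export
read_covariates <- function(path, counts = NULL, tol = 0.01) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "site_id"
  if (!is.null(counts)) {
    have <- as.character(df$site_id); want <- as.character(counts$site_ids)
    orphans <- c(setdiff(have, want), setdiff(want, have))
    if (length(orphans))
      stop("site ids do not match the count matrix: ",
           paste(orphans, collapse = ", "))
    df <- df[match(want, have), , drop = FALSE]
    rownames(df) <- NULL
  }
  covs <- site_covariates(df)
  num <- covariate_names(covs)
  mu <- vapply(covs[num], mean, numeric(1))
  s <- vapply(covs[num], sd, numeric(1))
  if (all(abs(mu) < tol) && all(abs(s - 1) < tol)) {
    attr(covs, "standardized") <- TRUE
    return(covs)
  }
  standardize_covariates(covs)
}

#' Write a covariate table to CSV
#' @param covs a [site_covariates()] table.
#' @param path output file.
#' @export
write_covariates <- function(covs, path) {
  write.csv(as.data.frame(covs), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read photo events / camera deployments
#'
#' Events: `camera_id`, `timestamp` (ISO-8601), `species`.  Deployments:
#' `camera_id`, `site_id`, `active_start`, `active_end`, `trap_nights`;
#' `trap_nights` must not exceed the active span.
#'
#' @param path CSV file.
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("camera_id", "timestamp", "species")
  if (!all(need %in% names(df)))
    stop("event CSV needs columns: ", paste(need, collapse = ", "))
  df$timestamp <- parse_timestamps(df$timestamp)
  df
}

#' @rdname read_events
#' @export
read_deployments <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("camera_id", "site_id", "active_start", "active_end")
  if (!all(need %in% names(df)))
    stop("deployment CSV needs columns: ", paste(need, collapse = ", "))
  df$active_start <- as.Date(df$active_start)
  df$active_end <- as.Date(df$active_end)
  span <- as.integer(df$active_end - df$active_start) + 1L
  if (is.null(df$trap_nights)) df$trap_nights <- span
  if (any(df$trap_nights > span))
    stop("trap_nights exceeds the active span for camera(s): ",
         paste(df$camera_id[df$trap_nights > span], collapse = ", "))
  per_site <- table(df$site_id)
  if (any(per_site > 4))
    warning("site(s) with more than 4 cameras: ",
            paste(names(per_site)[per_site > 4], collapse = ", "))
  df
}

#' Write an AIC model-selection table to CSV
#'
#' Columns: `model`, `nPars`, `AIC`, `dAIC`, `AICwt`, `cumltvWt`.
#'
#' @param tab an `aic_table` from [rank_models()].
#' @param path output file.
#' @export
write_aic_table <- function(tab, path) {
  out <- as.data.frame(tab)[c("model", "nPars", "AIC", "dAIC", "AICwt",
                              "cumltvWt")]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a goodness-of-fit report to CSV
#'
#' One row: statistic name, observed value, p-value, c-hat, iterations,
#' failures and the seed.
#'
#' @param gof a `gof_result`.
#' @param path output file.
#' @export
write_gof_report <- function(gof, path) {
  write.csv(data.frame(statistic = gof$statistic_name,
                       observed = gof$observed, p_value = gof$p_value,
                       c_hat = gof$c_hat, n_boot = gof$n_boot,
                       n_fail = gof$n_fail,
                       seed = if (is.null(gof$seed)) NA else gof$seed),
            path, row.names = FALSE)
  invisible(path)
}
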