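#' A partial or complete demographic time coordinate
#'
#' Holds any subset of the six demographic time measures for one
#' person-moment: chronological age `A`, period `P`, birth cohort `C`,
#' thanatological age `T`, death cohort `D`, lifespan `L`, all in decimal
#' years; unset measures are `NA`. The measures are linked by four triad
#' identities: A = P - C, T = D - P, L = D - C, L = A + T.
#'
#' @param A,P,C,T,D,L numeric scalars or `NA`.
#' @return object of class `demo_coord` (named numeric of length 6).
#' @export
#' @examples
#' complete_coord(demo_coord(T = 30, P = 1971))  # fills D = 2001
demo_coord <- function(A = NA, P = NA, C = NA, T = NA, D = NA, L = NA) {
  v <- c(A = as.numeric(A), P = as.numeric(P), C = as.numeric(C),
         T = as.numeric(T), D = as.numeric(D), L = as.numeric(L))
  if (length(v) != 6L)
    .stop_demotime("each measure must be a single value", "demotime_invalid")
  if (any(is.infinite(v) | is.nan(v)))
    .stop_demotime("measures must be finite or NA", "demotime_invalid")
  structure(v, class = "demo_coord")
}

as_demo_coord <- function(x) {
  if (inherits(x, "demo_coord")) return(x)
  if (is.numeric(x) && !is.null(names(x)) && all(names(x) %in% .MEASURES)) {
    args <- as.list(x)
    return(do.call(demo_coord, args))
  }
  if (is.list(x) && all(names(x) %in% .MEASURES))
    return(do.call(demo_coord, x))
  .stop_demotime("cannot interpret input as a demographic coordinate",
                 "demotime_invalid")
}

#' @export
print.demo_coord <- function(x, ...) {
  v <- unclass(x)
  set <- !is.na(v)
  cat("Demographic time coordinate\n")
  if (!any(set)) {
    cat("  (no measures set)\n")
  } else {
    cat(paste(sprintf("  %s = %.6g", names(v)[set], v[set]), collapse = "\n"),
        "\n")
  }
  if (any(!set)) cat("  unset:", paste(names(v)[!set], collapse = ", "), "\n")
  invisible(x)
}

#' Complete a partial coordinate through the triad identities
#'
#' Applies the four identity equations (A = P - C, T = D - P, L = D - C,
#' L = A + T) repeatedly until a fixed point: every derivable measure is
#' filled in, non-derivable measures stay `NA`. The operation is
#' idempotent. Supplied measures that contradict an identity beyond `eps`
#' raise an inconsistency error naming the identity; a negative age,
#' thanatological age, or lifespan (supplied or derived) raises a domain
#' error, since the demographic interpretation requires C <= P <= D.
#'
#' @param coord a [demo_coord()] (or named numeric/list coercible to one).
#' @param eps numeric tolerance in years for identity residuals
#'   (default `1e-9`; raise it for real, rounded data).
#' @return the completed `demo_coord`.
#' @export
#' @examples
#' complete_coord(demo_coord(C = 1893, D = 1964))  # L = 71
#' complete_coord(demo_coord(A = 1, P = 2, T = 3)) # C = 1, D = 5, L = 4
complete_coord <- function(coord, eps = 1e-9) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    .stop_demotime("`eps` must be a positive scalar", "demotime_invalid")
  v <- unclass(as_demo_coord(coord))
  repeat {
    changed <- FALSE
    for (nm in names(.IDENTITIES)) {
      id <- .IDENTITIES[[nm]]
      s <- v[[id[["sum"]]]]; a <- v[[id[["a"]]]]; b <- v[[id[["b"]]]]
      known <- !is.na(c(s, a, b))
      if (all(known)) {
        if (abs(s - a - b) > eps)
          .stop_demotime(
            sprintf("inconsistent coordinate: %s identity violated (%s = %s + %s, residual %.6g)",
                    nm, id[["sum"]], id[["a"]], id[["b"]], s - a - b),
            "demotime_inconsistency")
      } else if (sum(known) == 2L) {
        if (is.na(s)) v[[id[["sum"]]]] <- a + b
        else if (is.na(a)) v[[id[["a"]]]] <- s - b
        else v[[id[["b"]]]] <- s - a
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (m in c("A", "T", "L"))
    if (!is.na(v[[m]]) && v[[m]] < -eps)
      .stop_demotime(sprintf("negative %s (%.6g): demographic measures require C <= P <= D",
                             m, v[[m]]), "demotime_domain")
  structure(v, class = "demo_coord")
}

#' Which measures can be derived from a given set?
#'
#' Transitive closure of derivability under the four triad identities.
#' Two members of a triad determine the third; any three independent
#' measures including a calendar anchor (P, C, or D) determine all six.
#' TAL alone contains no calendar measure, so nothing further follows
#' from it.
#'
#' @param given character vector of measure labels (subset of
#'   A, P, C, T, D, L).
#' @return sorted character vector of the additional derivable labels
#'   (possibly empty).
#' @export
#' @examples
#' derivable_set(c("A", "P"))       # "C"
#' derivable_set(c("T", "A", "L"))  # character(0)
derivable_set <- function(given) {
  given <- unique(as.character(given))
  bad <- setdiff(given, .MEASURES)
  if (length(bad))
    .stop_demotime(paste("unknown measure label(s):", paste(bad, collapse = ", ")),
                   "demotime_invalid")
  known <- given
  repeat {
    added <- FALSE
    for (id in .IDENTITIES) {
      members <- unname(id)
      miss <- setdiff(members, known)
      if (length(miss) == 1L) {
        known <- c(known, miss)
        added <- TRUE
      }
    }
    if (!added) break
  }
  sort(setdiff(known, given))
}

#' List identity and ordering violations of a coordinate
#'
#' Unlike [complete_coord()] this never errors: it reports, for the
#' measures actually present, every triad identity whose residual exceeds
#' `eps`, every violation of the event ordering C <= P <= D, and any
#' negative duration measure (A, T, L).
#'
#' @param coord a [demo_coord()].
#' @param eps tolerance in years.
#' @return data frame with columns `check` and `residual`; zero rows when
#'   the coordinate is consistent.
#' @export
check_consistency <- function(coord, eps = 1e-9) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    .stop_demotime("`eps` must be a positive scalar", "demotime_invalid")
  v <- unclass(as_demo_coord(coord))
  checks <- character(0)
  res <- numeric(0)
  for (nm in names(.IDENTITIES)) {
    id <- .IDENTITIES[[nm]]
    s <- v[[id[["sum"]]]]; a <- v[[id[["a"]]]]; b <- v[[id[["b"]]]]
    if (!anyNA(c(s, a, b)) && abs(s - a - b) > eps) {
      checks <- c(checks, nm)
      res <- c(res, s - a - b)
    }
  }
  ord <- list(c("C", "P"), c("P", "D"), c("C", "D"))
  for (o in ord) {
    lo <- v[[o[1]]]; hi <- v[[o[2]]]
    if (!anyNA(c(lo, hi)) && lo - hi > eps) {
      checks <- c(checks, paste0(o[1], "<=", o[2]))
      res <- c(res, lo - hi)
    }
  }
  for (m in c("A", "T", "L")) {
    if (!is.na(v[[m]]) && v[[m]] < -eps) {
      checks <- c(checks, paste0(m, ">=0"))
      res <- c(res, v[[m]])
    }
  }
  data.frame(check = checks, residual = res, stringsAsFactors = FALSE)
}

#' Complete every row of a measure table
#'
#' Vectorised wrapper around [complete_coord()]: takes a data frame whose
#' columns are any subset of A, P, C, T, D, L (other columns pass
#' through) and returns it with all six measure columns, derivable cells
#' filled in.
#'
#' @param df data frame with at least one measure column.
#' @param eps tolerance in years, see [complete_coord()].
#' @return data frame with all six measure columns appended/updated.
#' @export
derive_measures <- function(df, eps = 1e-9) {
  stopifnot(is.data.frame(df))
  have <- intersect(.MEASURES, names(df))
  if (!length(have))
    .stop_demotime("no measure columns (A, P, C, T, D, L) found",
                   "demotime_invalid")
  out <- df
  for (m in setdiff(.MEASURES, have)) out[[m]] <- NA_real_
  for (r in seq_len(nrow(out))) {
    cc <- do.call(demo_coord, as.list(out[r, .MEASURES]))
    done <- complete_coord(cc, eps = eps)
    out[r, .MEASURES] <- as.list(unclass(done))
  }
  out
}
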