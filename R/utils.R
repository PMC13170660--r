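#' @keywords internal
"_PACKAGE"

## Argument checks -----------------------------------------------------------

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("iq_invalid_parameter", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(name, " must be a single finite number")
  }
  if (strict_lower) {
    if (x <= lower) stop_invalid(name, " must be > ", lower, " (got ", x, ")")
  } else if (x < lower) {
    stop_invalid(name, " must be >= ", lower, " (got ", x, ")")
  }
  if (x > upper) stop_invalid(name, " must be <= ", upper, " (got ", x, ")")
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(name, " must be TRUE or FALSE")
  }
  invisible(x)
}

## Seeds ---------------------------------------------------------------------

#' Derive reproducible child seeds from a master seed
#'
#' Every stochastic operation in the package takes an explicit integer seed.
#' Pipelines that need several independent streams derive them from a single
#' run-level master seed with this helper, so that one integer reproduces a
#' whole run.
#'
#' @param master_seed Single integer.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seeds(42, 3)
derive_seeds <- function(master_seed, n) {
  check_number(master_seed, "master_seed")
  check_number(n, "n", lower = 1)
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

## Connected components ------------------------------------------------------

# Two-pass union-find labelling of a binary mask. EBImage::bwlabel is
# 4-connected; puncta segmentation here uses 8-connectivity, so this is
# implemented directly. Returns an integer matrix of labels (0 = background).
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) stop_invalid("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(labels)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # scan in column-major order: neighbours already visited are those with
  # smaller linear index
  for (p in fg) {
    r <- ((p - 1L) %% nr) + 1L
    cc <- ((p - 1L) %/% nr) + 1L
    nb <- integer(0)
    if (r > 1L && labels[p - 1L] > 0L) nb <- c(nb, labels[p - 1L])
    if (cc > 1L) {
      q <- p - nr
      if (labels[q] > 0L) nb <- c(nb, labels[q])
      if (connectivity == 8) {
        if (r > 1L && labels[q - 1L] > 0L) nb <- c(nb, labels[q - 1L])
        if (r < nr && labels[q + 1L] > 0L) nb <- c(nb, labels[q + 1L])
      }
    }
    if (length(nb) == 0L) {
      parent <- c(parent, length(parent) + 1L)
      labels[p] <- length(parent)
    } else {
      roots <- vapply(unique(nb), find_root, integer(1))
      keep <- min(roots)
      labels[p] <- keep
      for (rt in roots) parent[rt] <- keep
    }
  }
  # second pass: resolve + compact label ids
  roots <- vapply(seq_along(parent), find_root, integer(1))
  compact <- integer(length(parent))
  compact[sort(unique(roots))] <- seq_along(unique(roots))
  labels[fg] <- compact[roots[labels[fg]]]
  labels
}

## Misc ----------------------------------------------------------------------

# linear-interpolation percentile (R quantile type 7); the convention used by
# every percentile in the package and documented in the methods vignette
percentile <- function(x, p) {
  unname(stats::quantile(x, p, type = 7, names = FALSE))
}
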