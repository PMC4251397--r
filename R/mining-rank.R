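# Attribute selection: supervised entropy-minimization discretization with
# the MDL stopping rule, information gain in bits, and merit ranking.

#' @noRd
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' @noRd
class_entropy <- function(labels) entropy_bits(table(labels))

# Recursive entropy-minimization binary splitting with the MDL criterion.
# Returns a sorted vector of cut points (possibly empty).
#' @noRd
mdl_cuts <- function(values, labels) {
  o <- order(values)
  v <- values[o]; y <- as.character(labels[o])
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 4) return(numeric(0))
    vv <- v[lo:hi]; yy <- y[lo:hi]
    ent <- entropy_bits(table(yy))
    if (ent == 0) return(numeric(0))
    # candidate cuts at boundaries between distinct values
    idx <- which(diff(vv) > 0)
    if (!length(idx)) return(numeric(0))
    best <- NULL; best_e <- Inf
    for (i in idx) {
      e <- (i * entropy_bits(table(yy[1:i])) +
              (n - i) * entropy_bits(table(yy[(i + 1):n]))) / n
      if (e < best_e) { best_e <- e; best <- i }
    }
    gain <- ent - best_e
    k <- length(unique(yy))
    k1 <- length(unique(yy[1:best]))
    k2 <- length(unique(yy[(best + 1):n]))
    e1 <- entropy_bits(table(yy[1:best]))
    e2 <- entropy_bits(table(yy[(best + 1):n]))
    delta <- log2(3^k - 2) - (k * ent - k1 * e1 - k2 * e2)
    accept <- gain > (log2(n - 1) + delta) / n
    if (!accept) return(numeric(0))
    cut <- (vv[best] + vv[best + 1]) / 2
    c(recurse(lo, lo + best - 1), cut, recurse(lo + best, hi))
  }
  sort(recurse(1, length(v)))
}

#' Supervised discretization of a numeric attribute
#'
#' Entropy-minimization binary splitting with the minimum-description-length
#' stopping rule. When no cut is accepted the attribute collapses to a
#' single bin (merit 0 under [info_gain()]).
#'
#' @param values Numeric attribute values.
#' @param labels Class labels aligned with `values`.
#' @return Numeric vector of cut points (possibly empty), the bin edges
#'   excluding the outer infinities.
#' @export
discretize <- function(values, labels) {
  ok <- !is.na(values)
  if (!sum(ok)) return(numeric(0))
  mdl_cuts(values[ok], labels[ok])
}

#' Information gain (merit) of an attribute
#'
#' `H(class) - H(class | binned attribute)` in bits, with numeric attributes
#' discretized by [discretize()] and missing values assigned to a dedicated
#' bin. For a binary class the merit is bounded by 1 bit.
#'
#' @param feature_values Numeric (or factor) attribute values.
#' @param class_labels Class labels.
#' @param cuts Optional precomputed cut points for numeric attributes.
#' @return Merit in bits (>= 0).
#' @export
info_gain <- function(feature_values, class_labels, cuts = NULL) {
  y <- as.character(class_labels)
  if (length(unique(y)) < 2) {
    warning("single-class input: merit is 0")
    return(0)
  }
  if (is.numeric(feature_values)) {
    if (is.null(cuts)) cuts <- discretize(feature_values, y)
    bins <- if (length(cuts))
      findInterval(feature_values, cuts)
    else
      rep(0L, length(feature_values))
    bins[is.na(feature_values)] <- -1L
  } else {
    bins <- as.character(feature_values)
    bins[is.na(bins)] <- ".missing"
  }
  h <- class_entropy(y)
  cond <- 0
  n <- length(y)
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + sum(sel) / n * entropy_bits(table(y[sel]))
  }
  max(h - cond, 0)
}

#' Rank feature-table attributes by information gain
#'
#' Computes the merit of every numeric attribute against the class column,
#' ranks them in descending order (ties broken alphabetically), and discards
#' attributes below the merit threshold.
#'
#' @param table An `apw_feature_table` with a `class` column.
#' @param threshold Merit threshold below which attributes are discarded
#'   (default 0.1).
#' @return Data frame with `name`, `merit`, `rank`, `selected`; the
#'   selected attributes first.
#' @export
rank_features <- function(table, threshold = 0.1) {
  stopifnot("class" %in% names(table))
  y <- table$class
  if (length(unique(y[!is.na(y)])) < 2)
    stop("ranking requires at least two classes")
  feats <- setdiff(names(table), c("class", "subject"))
  feats <- feats[vapply(table[feats], is.numeric, TRUE)]
  merit <- vapply(feats, function(f) info_gain(table[[f]], y), 0)
  o <- order(-merit, feats)
  out <- data.frame(name = feats[o], merit = merit[o],
                    rank = seq_along(feats),
                    selected = merit[o] >= threshold,
                    row.names = NULL)
  if (!any(out$selected))
    stop("all attributes fall below the merit threshold of ", threshold,
         "; consider lowering it")
  out
}
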