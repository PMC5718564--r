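# Integer-partition combinatorics underlying fragmentation patterns.
#
# A fragmentation pattern is an integer partition: the multiset of offspring
# group sizes produced when a parent group breaks apart. Partitions are kept
# in canonical form (parts sorted non-increasing) so that two patterns are
# equal iff their part vectors are identical.

#' Create a fragmentation pattern (integer partition)
#'
#' A partition is stored as an integer vector of parts in canonical,
#' non-increasing order. The class carries no further structure: the sum of
#' the parts is the size of the fragmenting group (before any fragmentation
#' cost) and the number of parts is the number of offspring groups.
#'
#' @param parts Vector of positive integers (any order; sorted internally).
#' @return An object of class `"partition"`: an integer vector sorted
#'   non-increasingly.
#' @examples
#' new_partition(c(1, 2, 1))  # canonicalised to 2+1+1
#' @seealso [parse_partition()], [format_partition()]
#' @export
new_partition <- function(parts) {
  if (length(parts) == 0) stop("a partition must have at least one part")
  if (any(is.na(parts)) || any(parts < 1) || any(parts != round(parts)))
    stop("partition parts must be positive integers")
  structure(sort(as.integer(parts), decreasing = TRUE), class = "partition")
}

#' @export
format.partition <- function(x, ...) paste(unclass(x), collapse = "+")

#' @export
print.partition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialise a partition as "a+b+c"
#'
#' @param kappa A `"partition"` or bare integer vector of parts.
#' @return A character scalar such as `"2+1+1"`.
#' @export
format_partition <- function(kappa) paste(as.integer(kappa), collapse = "+")

#' Parse a partition from its "a+b+c" string form
#'
#' @param x Character scalar, e.g. `"2+1+1"`.
#' @return A `"partition"` object.
#' @export
parse_partition <- function(x) {
  parts <- suppressWarnings(as.integer(strsplit(x, "+", fixed = TRUE)[[1]]))
  if (length(parts) == 0 || any(is.na(parts)))
    stop("cannot parse partition from ", sQuote(x))
  new_partition(parts)
}

#' Enumerate all partitions of an integer
#'
#' Partitions are generated in reverse-lexicographic order on their canonical
#' (non-increasing) form, e.g. for 4: `4`, `3+1`, `2+2`, `2+1+1`, `1+1+1+1`.
#' The order is deterministic and is used as the tie-breaking order for
#' fragmentation modes throughout the package.
#'
#' @param l Positive integer.
#' @param min_parts Keep only partitions with at least this many parts.
#' @return List of `"partition"` objects; length `count_partitions(l)` when
#'   `min_parts = 1`.
#' @examples
#' enumerate_partitions(4)
#' @export
enumerate_partitions <- function(l, min_parts = 1L) {
  l <- check_count(l, "l")
  rec <- function(rem, maxpart) {
    if (rem == 0L) return(list(integer(0)))
    out <- vector("list", 64L)
    nout <- 0L
    for (p in seq.int(min(rem, maxpart), 1L)) {
      for (tl in rec(rem - p, p)) {
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- c(p, tl)
      }
    }
    out[seq_len(nout)]
  }
  res <- rec(l, l)
  if (min_parts > 1L) res <- res[vapply(res, length, 0L) >= min_parts]
  lapply(res, function(p) structure(p, class = "partition"))
}

.partition_cache <- new.env(parent = emptyenv())

#' Count partitions of an integer (pentagonal-number recurrence)
#'
#' Computes the partition function by Euler's pentagonal-number recurrence
#' with memoisation, without enumerating partitions. All arithmetic is on
#' integers represented exactly in doubles; the counts needed here (up to
#' group size 50, p(50) = 204226) are far below the 2^53 exactness limit.
#'
#' @param l Positive integer.
#' @return The number of partitions of `l`.
#' @examples
#' count_partitions(4) # 5
#' @export
count_partitions <- function(l) {
  l <- check_count(l, "l")
  p <- get0("p", envir = .partition_cache, ifnotfound = 1)  # p[k+1] = count for k
  if (length(p) < l + 1) {
    from <- length(p)
    p <- c(p, numeric(l + 1 - length(p)))
    for (m in from:l) {
      acc <- 0
      k <- 1L
      repeat {
        g1 <- (k * (3L * k - 1L)) %/% 2L
        if (g1 > m) break
        sgn <- if (k %% 2L == 1L) 1 else -1
        acc <- acc + sgn * p[m - g1 + 1]
        g2 <- (k * (3L * k + 1L)) %/% 2L
        if (g2 <= m) acc <- acc + sgn * p[m - g2 + 1]
        k <- k + 1L
      }
      p[m + 1] <- acc
    }
    assign("p", p, envir = .partition_cache)
  }
  p[l + 1]
}

#' Multiplicity of a part in a partition
#'
#' Returns the number of parts of `kappa` equal to `i`, i.e. how many
#' offspring groups of size `i` the pattern produces.
#'
#' @param kappa A `"partition"` (or integer vector of parts).
#' @param i Positive integer part size.
#' @return Non-negative integer count (0 when `i` exceeds every part).
#' @export
part_multiplicity <- function(kappa, i) {
  i <- check_count(i, "i")
  sum(as.integer(kappa) == i)
}

#' Multiplicity vector of a partition
#'
#' @param kappa A `"partition"`.
#' @param nbins Length of the returned vector (part sizes 1..nbins).
#' @return Integer vector `m` with `m[i]` = number of parts equal to `i`.
#' @keywords internal
multiplicity_vector <- function(kappa, nbins) tabulate(as.integer(kappa), nbins)

#' Is a partition binary?
#'
#' Binary fragmentation splits a group into exactly two offspring groups;
#' binary patterns are the only ones that can be optimal when fragmentation
#' is costless or carries a proportional cost.
#'
#' @param kappa A `"partition"`.
#' @return `TRUE` iff the partition has exactly two parts.
#' @export
is_binary <- function(kappa) length(kappa) == 2L

# validate a positive integer scalar
check_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 1 || x != round(x))
    stop(sQuote(name), " must be a positive integer, got ", deparse(x))
  as.integer(x)
}
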