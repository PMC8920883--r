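#' Define a single subgroup
#'
#' A subgroup is the conjunction of one or more `factor = level` constraints,
#' at most one per factor. Constraints are stored in canonical order (factor
#' name, then level) so equal subgroups compare equal.
#'
#' @param ... Named arguments: `factor_name = "level"`.
#' @return A `subgroup`: a named character vector of constraints.
#' @export
#' @examples
#' subgroup(sex = "female", age_group = "4-6")
subgroup <- function(...) {
  cons <- c(...)
  if (length(cons) < 1L || is.null(names(cons)) || any(!nzchar(names(cons)))) {
    stop("a subgroup needs at least one named factor = level constraint")
  }
  if (anyDuplicated(names(cons))) {
    stop("a factor cannot be combined with itself: ",
         paste(names(cons)[duplicated(names(cons))], collapse = ", "))
  }
  cons <- cons[order(names(cons))]
  structure(as.character(cons), names = names(cons), class = "subgroup")
}

#' @export
print.subgroup <- function(x, ...) {
  cat("<subgroup> ", subgroup_key(x), "\n", sep = "")
  invisible(x)
}

#' Stable text key of a subgroup
#'
#' `"factor=level"` terms joined by `" + "`, in canonical (factor-name) order.
#' The key is byte-identical across runs and serves as the join key of all
#' result tables.
#'
#' @param sg A `subgroup`, or parallel character vectors via `factors`/`levels`.
#' @return Character scalar (or vector for the vectorised form).
#' @export
subgroup_key <- function(sg) {
  paste(paste0(names(sg), "=", as.character(sg)), collapse = " + ")
}

make_keys <- function(f1, l1, f2 = NULL, l2 = NULL) {
  k <- paste0(f1, "=", l1)
  if (!is.null(f2)) {
    two <- !is.na(f2)
    k[two] <- paste0(k[two], " + ", f2[two], "=", l2[two])
  }
  k
}

#' Enumerate all subgroups of a catalogue up to a depth cap
#'
#' Produces every 1-factorial subgroup (one level of one factor), every
#' 2-factorial subgroup (one level from each of two distinct factors), and so
#' on up to `depth` constraints. Enumeration is purely combinatorial: a
#' subgroup that happens to have no members in a given cohort (an "empty
#' cell") is still enumerated, so result tables keep a stable shape.
#'
#' Ordering is canonical and deterministic: by depth, then factor-name
#' combination (lexicographic), then declared level order.
#'
#' @param catalog A `factor_catalog`.
#' @param depth Depth cap `D >= 1`; the default 2 keeps subgroups
#'   interpretable and limits overlap.
#' @return A `subgroup_set`: a data.frame with columns `key`, `depth`, and
#'   `factor1`, `level1`, ..., `factorD`, `levelD` (NA-padded).
#' @export
#' @examples
#' cat2 <- factor_catalog(fct_def("sex", c("m", "f")),
#'                        fct_def("age", c("a", "b", "c", "d")))
#' nrow(enumerate_subgroups(cat2, depth = 2)) # 14
enumerate_subgroups <- function(catalog, depth = 2L) {
  stopifnot(inherits(catalog, "factor_catalog"))
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L) stop("depth cap must be >= 1")
  fnames <- sort(names(catalog))
  blocks <- list()
  for (d in seq_len(min(depth, length(fnames)))) {
    combos <- utils::combn(fnames, d, simplify = FALSE)
    for (fc in combos) {
      lv <- lapply(fc, function(f) catalog[[f]]$levels)
      # declared level order, first factor varying slowest
      grid <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)[, rev(seq_len(d)), drop = FALSE]
      names(grid) <- paste0("level", seq_len(d))
      grid <- grid[do.call(order, lapply(seq_len(d), function(i)
        match(grid[[i]], lv[[i]]))), , drop = FALSE]
      for (i in seq_len(d)) grid[[paste0("factor", i)]] <- fc[i]
      grid$depth <- d
      blocks[[length(blocks) + 1L]] <- grid
    }
  }
  maxd <- min(depth, length(fnames))
  cols <- c("depth", as.vector(rbind(paste0("factor", seq_len(maxd)),
                                     paste0("level", seq_len(maxd)))))
  blocks <- lapply(blocks, function(b) {
    for (cn in setdiff(cols, names(b))) b[[cn]] <- NA_character_
    b[cols]
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  key <- out$key <- vapply(seq_len(nrow(out)), function(i) {
    fs <- as.character(out[i, paste0("factor", seq_len(maxd))])
    ls <- as.character(out[i, paste0("level", seq_len(maxd))])
    ok <- !is.na(fs)
    paste(paste0(fs[ok], "=", ls[ok]), collapse = " + ")
  }, character(1L))
  if (anyDuplicated(key)) stop("internal error: duplicated subgroup keys")
  out <- out[c("key", setdiff(names(out), "key"))]
  structure(out, class = c("subgroup_set", "data.frame"),
            catalog = catalog, depth_cap = depth)
}

#' Closed-form count of subgroups up to a depth cap
#'
#' For depth cap 2 the count is `sum(l) + (sum(l)^2 - sum(l^2)) / 2`: all
#' single levels plus all cross-factor level pairs. General depth caps are
#' handled through elementary symmetric polynomials of the level counts
#' (`e_k` summed for `k = 1..D`), which agrees with brute-force enumeration.
#'
#' @param level_counts Integer vector, one level count (>= 1) per factor.
#' @param depth Depth cap `D >= 1`.
#' @return The number of subgroups, as a double (counts can be large).
#' @export
#' @examples
#' count_subgroups(c(2, 4), 2) # 14
count_subgroups <- function(level_counts, depth = 2L) {
  level_counts <- as.numeric(level_counts)
  stopifnot(all(level_counts >= 1), depth >= 1)
  depth <- min(as.integer(depth), length(level_counts))
  # e[k+1] holds the elementary symmetric polynomial e_k
  e <- c(1, rep(0, depth))
  for (l in level_counts) {
    kmax <- depth
    e[seq(kmax + 1L, 2L)] <- e[seq(kmax + 1L, 2L)] + l * e[seq(kmax, 1L)]
  }
  sum(e[-1L])
}

#' Subjects belonging to a subgroup
#'
#' @param sg A `subgroup`.
#' @param cohort A `cohort_table`.
#' @return Character vector of subject ids matching every constraint.
#' @export
members <- function(sg, cohort) {
  stopifnot(inherits(sg, "subgroup"), inherits(cohort, "cohort_table"))
  m <- cohort_meta(cohort)
  keep <- rep(TRUE, nrow(cohort))
  for (f in names(sg)) {
    fd <- m$catalog[[f]]
    if (is.null(fd)) stop("unknown factor in subgroup: ", f)
    if (!(sg[[f]] %in% fd$levels)) {
      stop("unknown level '", sg[[f]], "' for factor '", f, "'")
    }
    v <- cohort[[f]]
    keep <- keep & !is.na(v) & v == sg[[f]]
  }
  as.character(cohort[[m$id]][keep])
}

#' Subjects outside a subgroup (the complementary group)
#'
#' @inheritParams members
#' @return Character vector: all cohort ids minus [members()].
#' @export
complement <- function(sg, cohort) {
  m <- cohort_meta(cohort)
  setdiff(as.character(cohort[[m$id]]), members(sg, cohort))
}

#' Factorial context of a subgroup
#'
#' All subgroups over exactly the same factor set — the "siblings" of the
#' selected subgroup, one per level combination, the selected subgroup
#' included. For a 1-factorial subgroup on a k-level factor this is the k
#' levels of that factor.
#'
#' @param sg A `subgroup`.
#' @param catalog A `factor_catalog` declaring the constrained factors.
#' @return A list of `subgroup` objects in canonical order.
#' @export
factorial_context <- function(sg, catalog) {
  stopifnot(inherits(sg, "subgroup"), inherits(catalog, "factor_catalog"))
  fs <- names(sg)
  bad <- setdiff(fs, names(catalog))
  if (length(bad)) stop("subgroup factors not in catalogue: ",
                        paste(bad, collapse = ", "))
  lv <- lapply(fs, function(f) catalog[[f]]$levels)
  grid <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(fs)), drop = FALSE]
  names(grid) <- fs
  grid <- grid[do.call(order, lapply(seq_along(fs), function(i)
    match(grid[[i]], lv[[i]]))), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    do.call(subgroup, as.list(stats::setNames(as.character(grid[i, ]), fs)))
  })
}
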