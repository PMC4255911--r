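#' Pathway collections (GMT format)
#'
#' A pathway collection maps pathway ids to member sets (genes, proteins,
#' metabolites). Collections from different databases describe
#' overlapping biology under different names, so downstream grouping by
#' member overlap is used to unify them.
#'
#' @param pathways named list: pathway id -> character vector of members,
#'   or a list of `list(description=, members=)` entries.
#' @param descriptions optional character vector parallel to `pathways`.
#' @return object of class `pathway_collection` with fields `pathways`
#'   (named list of `list(description, members)`) and `universe` (union
#'   of all members).
#' @export
pathway_collection <- function(pathways, descriptions = NULL) {
  if (!length(pathways)) stop("empty pathway collection", call. = FALSE)
  ids <- names(pathways)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("pathways must be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id: ", sQuote(ids[duplicated(ids)][1]),
         call. = FALSE)
  }
  entries <- Map(function(p, i) {
    if (is.list(p)) {
      list(description = p$description %||% "",
           members = unique(as.character(p$members)))
    } else {
      list(description = if (!is.null(descriptions)) descriptions[[i]] else "",
           members = unique(as.character(p)))
    }
  }, pathways, seq_along(pathways))
  sizes <- vapply(entries, function(e) length(e$members), 0L)
  if (any(sizes == 0L)) {
    stop("pathway with empty member set: ",
         sQuote(ids[sizes == 0L][1]), call. = FALSE)
  }
  structure(list(pathways = setNames(entries, ids),
                 universe = sort(unique(unlist(
                   lapply(entries, `[[`, "members"))))),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- vapply(x$pathways, function(p) length(p$members), 0L)
  cat("<pathway_collection>", length(x$pathways), "pathways,",
      length(x$universe), "distinct members (set sizes ",
      min(sizes), "-", max(sizes), ")\n")
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' Broad-dialect GMT: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...` (at least 3 fields).
#' Duplicate members within a line are deduplicated; duplicate pathway
#' names are an error.
#'
#' @param path GMT file path.
#' @return `read_gmt()` returns a [pathway_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", sQuote(path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT line ", lineno[short][1], " has fewer than 3 fields",
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate pathway name ", sQuote(ids[duplicated(ids)][1]),
         " at GMT line ", lineno[duplicated(ids)][1], call. = FALSE)
  }
  pathway_collection(
    setNames(lapply(fields, function(f) {
      m <- f[-(1:2)]
      list(description = f[[2]], members = unique(m[nzchar(m)]))
    }), ids))
}

#' @rdname read_gmt
#' @param collection a [pathway_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(names(collection$pathways), function(id) {
    p <- collection$pathways[[id]]
    paste(c(id, p$description, p$members), collapse = "\t")
  }, "")
  atomic_write(path, function(tmp) {
    writeLines(lines, tmp, useBytes = TRUE)
  })
  invisible(path)
}

#' Jaccard index of two member sets
#'
#' `|A intersect B| / |A union B|` — the overlap measure between two
#' pathways' participants. 1 iff the sets are equal, 0 iff disjoint.
#'
#' @param a,b non-empty character vectors (treated as sets).
#' @return number in `[0, 1]`.
#' @examples
#' jaccard_index(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (!length(a) || !length(b)) {
    stop("jaccard_index is undefined for empty sets", call. = FALSE)
  }
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

# all pairwise Jaccard values of a collection, via the binary membership
# matrix (crossprod gives all intersection sizes at once)
pairwise_jaccard <- function(collection) {
  ids <- names(collection$pathways)
  M <- membership_matrix(collection$universe,
                         lapply(collection$pathways, `[[`, "members"))
  jaccard_from_membership(M)
}

membership_matrix <- function(universe, member_sets) {
  M <- matrix(0L, length(universe), length(member_sets),
              dimnames = list(NULL, names(member_sets)))
  for (j in seq_along(member_sets)) {
    M[match(member_sets[[j]], universe), j] <- 1L
  }
  M
}

# upper-triangle Jaccard values from a 0/1 membership matrix
jaccard_from_membership <- function(M) {
  inter <- crossprod(M)
  sizes <- diag(inter)
  un <- outer(sizes, sizes, "+") - inter
  J <- inter / un
  J[upper.tri(J)]
}

#' Permutation-null Jaccard threshold at a target FDR
#'
#' Estimates how much pathway overlap could arise by chance: each
#' permutation redraws every pathway's members uniformly without
#' replacement from the collection's member universe, preserving set
#' sizes, and all pairwise Jaccard values of the null collection are
#' recorded. For each candidate threshold `t` (the sorted observed
#' pairwise values), `FDR(t)` = (mean null count of pairs `>= t`) /
#' (observed count of pairs `>= t`); the smallest `t` with
#' `FDR(t) <= fdr` is returned. At `fdr = 0` this is the smallest
#' observed value strictly above every null value — the conservative
#' "0% FDR" cutoff. When no candidate achieves the target FDR the result
#' carries `admissible = FALSE` rather than raising an error.
#'
#' @param collection a [pathway_collection()] with `>= 2` pathways.
#' @param fdr target false discovery rate in `[0, 1]` (default 0).
#' @param n_perm number of null collections (default 1000).
#' @param seed RNG seed; the run is fully reproducible given it.
#' @return object of class `perm_threshold`: list with `threshold`
#'   (`NA` when inadmissible), `admissible`, `fdr`, `n_perm`, `max_null`
#'   (largest null Jaccard seen), `n_pairs`, `seed`.
#' @export
permutation_threshold <- function(collection, fdr = 0, n_perm = 1000L,
                                  seed = 17L) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (length(collection$pathways) < 2L) {
    stop("need at least 2 pathways", call. = FALSE)
  }
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (fdr < 0 || fdr > 1) stop("fdr must be in [0, 1]", call. = FALSE)

  members <- lapply(collection$pathways, `[[`, "members")
  sizes <- lengths(members)
  universe <- collection$universe
  nu <- length(universe)
  obs <- sort(pairwise_jaccard(collection))
  candidates <- unique(obs)

  null_vals <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    unlist(lapply(seq_len(n_perm), function(i) {
      M <- matrix(0L, nu, length(sizes))
      for (j in seq_along(sizes)) {
        M[sample.int(nu, sizes[[j]]), j] <- 1L
      }
      jaccard_from_membership(M)
    }), use.names = FALSE)
  })
  max_null <- if (length(null_vals)) max(null_vals) else 0
  null_sorted <- sort(null_vals)
  n_obs <- length(obs)

  threshold <- NA_real_
  for (t in candidates) {
    # counts of values >= t via sorted-vector position
    obs_ge <- n_obs - findInterval(t - 1e-12, obs)
    null_ge <- length(null_sorted) - findInterval(t - 1e-12, null_sorted)
    est_fdr <- (null_ge / n_perm) / obs_ge
    if (est_fdr <= fdr) {
      threshold <- t
      break
    }
  }
  structure(list(threshold = threshold, admissible = !is.na(threshold),
                 fdr = fdr, n_perm = as.integer(n_perm),
                 max_null = max_null, n_pairs = n_obs,
                 seed = as.integer(seed)),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  if (x$admissible) {
    cat(sprintf(
      "<perm_threshold> J >= %.4g at FDR <= %g (%d permutations, max null J = %.4g, seed %d)\n",
      x$threshold, x$fdr, x$n_perm, x$max_null, x$seed))
  } else {
    cat(sprintf(
      "<perm_threshold> no admissible threshold at FDR <= %g (%d permutations, max null J = %.4g)\n",
      x$fdr, x$n_perm, x$max_null))
  }
  invisible(x)
}

#' Group pathways by Jaccard overlap
#'
#' Connects every pathway pair whose Jaccard index is at least
#' `threshold` and reports the connected components of size `>= 2` as
#' groups; singletons are left ungrouped. Components (rather than
#' cliques) give the minimal-assumption partition of the thresholded
#' similarity graph, so redundant pathway entries from different source
#' databases collapse into one group.
#'
#' @param collection a [pathway_collection()].
#' @param threshold Jaccard threshold in `(0, 1]`, typically from
#'   [permutation_threshold()].
#' @return object of class `pathway_grouping`: list with `threshold`,
#'   `groups` (list of sorted pathway-id vectors, ordered by smallest
#'   member id), `ungrouped` (sorted ids), `null_summary` (the
#'   `perm_threshold` when one was passed).
#' @export
group_pathways <- function(collection, threshold) {
  stopifnot(inherits(collection, "pathway_collection"))
  null_summary <- NULL
  if (inherits(threshold, "perm_threshold")) {
    null_summary <- threshold
    if (!threshold$admissible) {
      stop("no admissible threshold; nothing to group", call. = FALSE)
    }
    threshold <- threshold$threshold
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  ids <- names(collection$pathways)
  J <- pairwise_jaccard(collection)
  pairs <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
  hit <- J >= threshold - 1e-12
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (any(hit)) {
    g <- igraph::add_edges(g, t(pairs[hit, , drop = FALSE]))
  }
  comp <- igraph::components(g)
  groups <- split(ids, comp$membership)
  big <- groups[lengths(groups) >= 2L]
  big <- lapply(big, sort)
  big <- big[order(vapply(big, `[[`, "", 1L))]
  ungrouped <- sort(unlist(groups[lengths(groups) < 2L], use.names = FALSE))
  structure(list(threshold = threshold, groups = unname(big),
                 ungrouped = as.character(ungrouped %||% character()),
                 null_summary = null_summary),
            class = "pathway_grouping")
}

#' @export
print.pathway_grouping <- function(x, ...) {
  n_in <- sum(lengths(x$groups))
  cat(sprintf(
    "<pathway_grouping> J >= %.4g: %d groups summarising %d pathways (%d ungrouped)\n",
    x$threshold, length(x$groups), n_in, length(x$ungrouped)))
  invisible(x)
}

#' Flatten a grouping to a table
#'
#' @param grouping a [group_pathways()] result.
#' @return data.frame with columns `pathway_id`, `group_id` (0 for
#'   ungrouped), `group_size`.
#' @export
grouping_table <- function(grouping) {
  stopifnot(inherits(grouping, "pathway_grouping"))
  rows <- c(
    lapply(seq_along(grouping$groups), function(i) {
      data.frame(pathway_id = grouping$groups[[i]], group_id = i,
                 group_size = length(grouping$groups[[i]]))
    }),
    if (length(grouping$ungrouped)) {
      list(data.frame(pathway_id = grouping$ungrouped, group_id = 0L,
                      group_size = 1L))
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
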