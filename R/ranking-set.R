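#' Grouped rankings of genotype subsets
#'
#' A `ranking_set` holds one best-first ordering per group (typically one
#' farmer field and season in a tricot trial, where each field ranks 3 test
#' genotypes plus a check). Orderings may cover different subsets of the item
#' pool and different numbers of items.
#'
#' @param orderings a list of character vectors (best first), or a character
#'   matrix with one ordering per row (`NA` padding for short orderings).
#' @param items optional character vector of all item ids; defaults to the
#'   sorted union of ordered items.
#' @param group optional data.frame with one row per ordering (e.g. columns
#'   `field_id`, `season`). A default `field_id` is created if absent.
#' @param weights positive per-ordering weights, default 1.
#' @param ties logical per-ordering flag marking orderings whose construction
#'   involved a broken tie (see [rank_from_measures()]).
#'
#' @return An object of class `ranking_set`: a list with elements `items`
#'   (character), `ord` (integer matrix, items coded by position in `items`,
#'   0 = padding), `group` (data.frame), `weights`, `ties`.
#' @examples
#' r <- ranking_set(list(c("A", "B", "C"), c("B", "A")))
#' r
#' @export
ranking_set <- function(orderings, items = NULL, group = NULL,
                        weights = NULL, ties = NULL) {
  if (is.matrix(orderings)) {
    orderings <- lapply(seq_len(nrow(orderings)), function(i) {
      v <- orderings[i, ]
      as.character(v[!is.na(v) & v != ""])
    })
  }
  if (!is.list(orderings) || length(orderings) == 0)
    stop("'orderings' must be a non-empty list of character vectors")
  orderings <- lapply(orderings, as.character)
  dup <- vapply(orderings, function(o) anyDuplicated(o) > 0, logical(1))
  if (any(dup))
    stop("duplicate items within ordering(s): ",
         paste(which(dup)[seq_len(min(5, sum(dup)))], collapse = ", "))
  used <- unique(unlist(orderings))
  if (is.null(items)) items <- sort(used)
  unknown <- setdiff(used, items)
  if (length(unknown))
    stop("ordered items not in 'items': ", paste(head(unknown, 5), collapse = ", "))
  n <- length(orderings)
  m <- max(lengths(orderings))
  ord <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    o <- match(orderings[[i]], items)
    if (length(o)) ord[i, seq_along(o)] <- o
  }
  if (is.null(group)) group <- data.frame(field_id = paste0("g", seq_len(n)))
  if (nrow(group) != n) stop("'group' must have one row per ordering")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(!is.finite(weights)) || any(weights <= 0))
    stop("'weights' must be positive, one per ordering")
  if (is.null(ties)) ties <- rep(FALSE, n)
  structure(list(items = items, ord = ord, group = group,
                 weights = as.numeric(weights), ties = ties),
            class = "ranking_set")
}

#' @export
print.ranking_set <- function(x, ...) {
  cat("ranking_set:", nrow(x$ord), "rankings of", length(x$items), "items\n")
  k <- min(3, nrow(x$ord))
  for (i in seq_len(k)) {
    o <- x$ord[i, ]
    cat(" ", paste(x$items[o[o > 0]], collapse = " > "), "\n")
  }
  if (nrow(x$ord) > k) cat("  ...\n")
  invisible(x)
}

#' @export
length.ranking_set <- function(x) nrow(x$ord)

#' Subset a ranking_set by record index
#' @param x a `ranking_set`; @param i record indices; @param ... unused.
#' @export
`[.ranking_set` <- function(x, i, ...) {
  structure(list(items = x$items, ord = x$ord[i, , drop = FALSE],
                 group = x$group[i, , drop = FALSE],
                 weights = x$weights[i], ties = x$ties[i]),
            class = "ranking_set")
}

#' Orderings of a ranking_set as a list of character vectors
#' @param r a `ranking_set`.
#' @return list of best-first character vectors.
#' @export
orderings <- function(r) {
  lapply(seq_len(nrow(r$ord)), function(i) {
    o <- r$ord[i, ]
    r$items[o[o > 0]]
  })
}

#' Build rankings from per-plot measurements
#'
#' Converts per-field plot measurements (e.g. grain yield in t/ha) into
#' best-first orderings. Exact ties are broken deterministically by
#' lexicographic item id and flagged in the result, since the Plackett-Luce
#' likelihood used downstream has no tie support; callers may drop or jitter
#' flagged fields.
#'
#' @param values data.frame with columns `field_id`, `item`, `value` and
#'   optionally `season`.
#' @param direction `"higher_is_better"` (e.g. yield) or `"lower_is_better"`.
#' @return a [ranking_set()] with `ties` flags set on fields where a tie was
#'   broken.
#' @examples
#' v <- data.frame(field_id = "f1", item = c("A", "B", "C", "D"),
#'                 value = c(4, 3.1, 2.2, 5))
#' orderings(rank_from_measures(v))[[1]]  # D A B C
#' @export
rank_from_measures <- function(values,
                               direction = c("higher_is_better",
                                             "lower_is_better")) {
  direction <- match.arg(direction)
  need <- c("field_id", "item", "value")
  if (!all(need %in% names(values)))
    stop("'values' needs columns field_id, item, value")
  if (!is.numeric(values$value)) stop("measurements must be numeric")
  if (any(!is.finite(values$value))) stop("measurements must be finite")
  fid <- as.character(values$field_id)
  fields <- unique(fid)
  ords <- vector("list", length(fields))
  tied <- logical(length(fields))
  seasons <- character(length(fields))
  has_season <- "season" %in% names(values)
  for (i in seq_along(fields)) {
    sub <- values[fid == fields[i], ]
    if (nrow(sub) < 2) stop("field ", fields[i], " has fewer than 2 items")
    v <- if (direction == "higher_is_better") -sub$value else sub$value
    ords[[i]] <- as.character(sub$item)[order(v, as.character(sub$item))]
    tied[i] <- anyDuplicated(sub$value) > 0
    if (has_season) seasons[i] <- as.character(sub$season[1])
  }
  group <- data.frame(field_id = fields)
  if (has_season) group$season <- seasons
  ranking_set(ords, group = group, ties = tied)
}

#' Pairwise win/loss expansion of a ranking_set
#'
#' Expands every ordering into all its implied pairwise comparisons: an
#' ordering of m items yields m(m-1)/2 directed wins.
#'
#' @param r a `ranking_set`.
#' @return data.frame with columns `winner`, `loser`, `count`.
#' @export
comparison_graph <- function(r) {
  n <- nrow(r$ord)
  acc_w <- vector("list", n); acc_l <- vector("list", n)
  for (i in seq_len(n)) {
    o <- r$ord[i, ]
    o <- o[o > 0]
    m <- length(o)
    if (m < 2) next
    pair_a <- rep(seq_len(m - 1), times = (m - 1):1)
    pair_b <- sequence((m - 1):1, from = 2:m)
    acc_w[[i]] <- o[pair_a]; acc_l[[i]] <- o[pair_b]
  }
  ow <- r$items[unlist(acc_w)]; ol <- r$items[unlist(acc_l)]
  if (!length(ow))
    return(data.frame(winner = character(0), loser = character(0),
                      count = integer(0)))
  tab <- aggregate(list(count = rep(1L, length(ow))),
                   by = list(winner = ow, loser = ol), FUN = sum)
  tab[order(tab$winner, tab$loser), , drop = FALSE]
}

#' Strong connectivity of the comparison network
#'
#' The Plackett-Luce maximum-likelihood estimate exists and is finite only
#' when the directed win/loss graph is strongly connected (every item both
#' wins and loses against the rest of the network, directly or indirectly).
#'
#' @param r a `ranking_set`.
#' @return list with `connected` (logical) and `membership` (named integer
#'   vector of strongly-connected component labels per item).
#' @export
check_connectivity <- function(r) {
  if (!inherits(r, "ranking_set") || nrow(r$ord) == 0)
    stop("empty ranking_set")
  edges <- comparison_graph(r)
  g <- igraph::graph_from_data_frame(
    edges[, c("winner", "loser")], directed = TRUE,
    vertices = data.frame(name = r$items))
  comp <- igraph::components(g, mode = "strong")
  membership <- comp$membership[r$items]
  list(connected = comp$no == 1L,
       membership = setNames(as.integer(membership), r$items))
}

#' Read and write grouped rankings as CSV
#'
#' Long dialect: columns `field_id`, `season`, `item`, `rank` (rank 1 = best).
#' Wide dialect: columns `field_id`, `season`, `item_1..item_k`,
#' `rank_1..rank_k`. Both are UTF-8 with a header.
#'
#' @param path file path.
#' @param dialect `"long"` or `"wide"`.
#' @return [read_rankings()] returns a `ranking_set`; [write_rankings()]
#'   returns `path` invisibly. `write_rankings` followed by `read_rankings`
#'   is the identity on the ranking content.
#' @export
read_rankings <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "long") {
    need <- c("field_id", "item", "rank")
    if (!all(need %in% names(d)))
      stop("long dialect needs columns field_id, item, rank")
    fid <- as.character(d$field_id)
    fields <- unique(fid)
    ords <- vector("list", length(fields))
    seasons <- character(length(fields))
    for (i in seq_along(fields)) {
      rows <- which(fid == fields[i])
      sub <- d[rows, ]
      if (anyDuplicated(sub$item))
        stop("duplicate item in field ", fields[i], " (rows ",
             paste(rows[duplicated(sub$item) | duplicated(sub$item, fromLast = TRUE)],
                   collapse = ","), ")")
      rk <- sort(sub$rank)
      if (!identical(as.integer(rk), seq_len(nrow(sub))))
        stop("rank gap or duplicate rank in field ", fields[i], " (rows ",
             paste(rows, collapse = ","), ")")
      ords[[i]] <- as.character(sub$item)[order(sub$rank)]
      if ("season" %in% names(d)) seasons[i] <- as.character(sub$season[1])
    }
    group <- data.frame(field_id = fields)
    if ("season" %in% names(d)) group$season <- seasons
    ranking_set(ords, group = group)
  } else {
    icols <- grep("^item_[0-9]+$", names(d), value = TRUE)
    rcols <- grep("^rank_[0-9]+$", names(d), value = TRUE)
    if (!length(icols) || length(icols) != length(rcols))
      stop("wide dialect needs matched item_k / rank_k columns")
    icols <- icols[order(as.integer(sub("item_", "", icols)))]
    rcols <- rcols[order(as.integer(sub("rank_", "", rcols)))]
    ords <- vector("list", nrow(d))
    for (i in seq_len(nrow(d))) {
      it <- as.character(unlist(d[i, icols]))
      rk <- as.numeric(unlist(d[i, rcols]))
      keep <- !is.na(it) & it != "" & !is.na(rk)
      it <- it[keep]; rk <- rk[keep]
      if (anyDuplicated(it)) stop("duplicate item in row ", i)
      if (!identical(as.integer(sort(rk)), seq_along(rk)))
        stop("rank gap in row ", i)
      ords[[i]] <- it[order(rk)]
    }
    group <- data.frame(field_id = as.character(d$field_id))
    if ("season" %in% names(d)) group$season <- as.character(d$season)
    ranking_set(ords, group = group)
  }
}

#' @param r a `ranking_set` to write.
#' @rdname read_rankings
#' @export
write_rankings <- function(r, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  os <- orderings(r)
  season <- if ("season" %in% names(r$group)) r$group$season else
    rep(NA_character_, length(os))
  if (dialect == "long") {
    d <- do.call(rbind, lapply(seq_along(os), function(i) {
      data.frame(field_id = r$group$field_id[i], season = season[i],
                 item = os[[i]], rank = seq_along(os[[i]]))
    }))
    write.csv(d, path, row.names = FALSE)
  } else {
    k <- max(lengths(os))
    rows <- lapply(seq_along(os), function(i) {
      o <- c(os[[i]], rep(NA, k - length(os[[i]])))
      rk <- c(seq_along(os[[i]]), rep(NA, k - length(os[[i]])))
      out <- data.frame(field_id = r$group$field_id[i], season = season[i])
      for (j in seq_len(k)) out[[paste0("item_", j)]] <- o[j]
      for (j in seq_len(k)) out[[paste0("rank_", j)]] <- rk[j]
      out
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}
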