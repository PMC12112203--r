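#' Read a triple file
#'
#' Parses a tab-separated triple file (`head<TAB>relation<TAB>tail`, one
#' triple per line, UTF-8, the dialect used by the standard link-prediction
#' benchmarks). Labels are case-sensitive; trailing whitespace on each line
#' is trimmed. Duplicate triples are dropped with a message; the number
#' dropped is attached as attribute `"n_duplicates"`.
#'
#' @param path Path to a triple file.
#' @param quiet Suppress the duplicate-count message.
#' @return A tibble with character columns `head`, `relation`, `tail`, in
#'   file order (before deduplication order is preserved).
#' @seealso [write_triples()], [kg_build()]
#' @export
read_triples <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such triple file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  keep <- nzchar(lines)
  if (!any(keep)) {
    out <- tibble::tibble(head = character(), relation = character(),
                          tail = character())
    attr(out, "n_duplicates") <- 0L
    return(out)
  }
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    bad <- idx[which(nf != 3L)[1L]]
    stop(sprintf("malformed line %d in %s: expected 3 tab-separated fields, got %d",
                 bad, path, nf[which(nf != 3L)[1L]]), call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  out <- tibble::tibble(head = m[, 1L], relation = m[, 2L], tail = m[, 3L])
  dup <- duplicated(out)
  if (any(dup)) {
    if (!quiet) message(sum(dup), " duplicate triple(s) dropped from ", basename(path))
    out <- out[!dup, ]
  }
  attr(out, "n_duplicates") <- sum(dup)
  out
}

#' Write a triple file
#'
#' Writes triples as UTF-8 TSV with LF line endings, the inverse of
#' [read_triples()].
#'
#' @param triples A tibble with columns `head`, `relation`, `tail` (character).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triples <- function(triples, path) {
  stopifnot(all(c("head", "relation", "tail") %in% names(triples)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(triples$head, triples$relation, triples$tail, sep = "\t"),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

index_triples <- function(df, ent_index, rel_index) {
  tibble::tibble(
    h = unname(ent_index[df$head]),
    r = unname(rel_index[df$relation]),
    t = unname(ent_index[df$tail])
  )
}

#' Build a knowledge graph from triple tables
#'
#' Assembles the central knowledge-graph object: the entity/relation
#' vocabulary (built from the training split in first-appearance order),
#' indexed train/valid/test triple sets, and bookkeeping for filtered
#' evaluation. Validation/test triples naming an entity or relation unseen
#' in training are excluded (with a message) and counted in `$n_skipped` —
#' they cannot be scored by an embedding model.
#'
#' Reciprocal augmentation, the neighbour index and the filter map are added
#' by [kg_add_reciprocals()].
#'
#' @param train,valid,test Tibbles of character triples as returned by
#'   [read_triples()]; `valid`/`test` may be `NULL` or empty.
#' @param quiet Suppress messages about skipped triples.
#' @return An object of class `semlink_kg`: a list with `entities`,
#'   `relations` (character vectors; index = position), `n_rel_base`,
#'   `train`/`valid`/`test` (tibbles of integer columns `h`, `r`, `t`),
#'   `reciprocal` flag, and `n_skipped`.
#' @examples
#' tr <- tibble::tibble(head = c("a", "b"), relation = "likes", tail = c("b", "c"))
#' kg <- kg_build(tr)
#' kg$entities
#' @export
kg_build <- function(train, valid = NULL, test = NULL, quiet = FALSE) {
  stopifnot(nrow(train) > 0)
  empty <- tibble::tibble(head = character(), relation = character(), tail = character())
  valid <- valid %||% empty
  test <- test %||% empty

  # first-appearance order: scan head then tail within each row block
  ents <- unique(as.vector(rbind(train$head, train$tail)))
  rels <- unique(train$relation)
  if (any(!nzchar(ents)) || any(!nzchar(rels))) {
    stop("empty entity or relation label in training triples", call. = FALSE)
  }
  ent_index <- stats::setNames(seq_along(ents), ents)
  rel_index <- stats::setNames(seq_along(rels), rels)

  filter_split <- function(df, tag) {
    ok <- df$head %in% ents & df$tail %in% ents & df$relation %in% rels
    if (any(!ok) && !quiet) {
      message(sum(!ok), " ", tag, " triple(s) skipped (entity/relation unseen in train)")
    }
    list(idx = index_triples(df[ok, ], ent_index, rel_index), skipped = sum(!ok))
  }
  v <- filter_split(valid, "valid")
  te <- filter_split(test, "test")

  structure(
    list(
      entities = ents,
      relations = rels,
      n_rel_base = length(rels),
      train = index_triples(train, ent_index, rel_index),
      valid = v$idx,
      test = te$idx,
      reciprocal = FALSE,
      n_skipped = c(valid = v$skipped, test = te$skipped),
      edges = NULL,
      filter_map = NULL
    ),
    class = "semlink_kg"
  )
}

#' Load a knowledge-graph dataset directory
#'
#' Reads `train.txt`, `valid.txt` and `test.txt` from `dir` (the layout of
#' the standard link-prediction benchmarks) and builds the graph with
#' [kg_build()].
#'
#' @param dir Dataset directory.
#' @param quiet Suppress messages.
#' @return A `semlink_kg` object.
#' @export
kg_load <- function(dir, quiet = FALSE) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_triples(p, quiet = quiet) else NULL
  }
  train <- rd("train.txt")
  if (is.null(train)) stop("no train.txt in ", dir, call. = FALSE)
  kg_build(train, rd("valid.txt"), rd("test.txt"), quiet = quiet)
}

#' Add reciprocal relations
#'
#' Appends a reciprocal relation `r_rev` for every relation `r` (doubling the
#' relation vocabulary) and, for every training triple `(h, r, t)`, the
#' reciprocal triple `(t, r_rev, h)`. This lets a single tail-prediction
#' scorer answer head queries: predicting the head of `(?, r, t)` is scored
#' as the tail query `(t, r_rev, ?)`. The neighbour index and the filter map
#' used by filtered evaluation are (re)built over the augmented graph.
#'
#' @param kg A `semlink_kg` from [kg_build()] / [kg_load()].
#' @return The augmented `semlink_kg` (relation count doubled,
#'   `$train` doubled, `$edges` and `$filter_map` populated).
#' @export
kg_add_reciprocals <- function(kg) {
  stopifnot(inherits(kg, "semlink_kg"))
  if (isTRUE(kg$reciprocal)) {
    stop("reciprocal relations already present", call. = FALSE)
  }
  nr <- kg$n_rel_base
  kg$relations <- c(kg$relations, paste0(kg$relations, "_rev"))
  rev_train <- tibble::tibble(h = kg$train$t, r = kg$train$r + nr, t = kg$train$h)
  kg$train <- dplyr::bind_rows(kg$train, rev_train)
  kg$reciprocal <- TRUE
  kg$edges <- build_neighbor_index(kg)
  kg$filter_map <- build_filter_map(kg)
  kg
}

#' Build the neighbour index
#'
#' For every entity `i`, enumerates the incoming augmented training edges:
#' the pairs `(e_j, r_j)` such that `(e_j, r_j, i)` is an augmented training
#' triple. These are the neighbourhoods over which the encoder's attention
#' aggregation runs. Order is deterministic: sorted by
#' `(centre, neighbour, relation)`.
#'
#' @param kg A reciprocal-augmented `semlink_kg` (or one being augmented).
#' @return A list with integer vectors `center`, `nbr`, `rel` (one element
#'   per edge, sorted by centre) and `ptr`, a length `n_ent + 1` offset
#'   vector: entity `i`'s edges occupy positions `ptr[i]:(ptr[i+1]-1)`
#'   (empty when `ptr[i] == ptr[i+1]`).
#' @export
build_neighbor_index <- function(kg) {
  if (!isTRUE(kg$reciprocal)) {
    stop("neighbour index requires reciprocal augmentation (kg_add_reciprocals)",
         call. = FALSE)
  }
  center <- kg$train$t
  nbr <- kg$train$h
  rel <- kg$train$r
  o <- order(center, nbr, rel)
  center <- center[o]; nbr <- nbr[o]; rel <- rel[o]
  n_ent <- length(kg$entities)
  counts <- tabulate(center, nbins = n_ent)
  list(center = center, nbr = nbr, rel = rel,
       ptr = c(1L, 1L + cumsum(counts)))
}

neighbors_of <- function(kg, i) {
  e <- kg$edges
  if (is.null(e)) stop("neighbour index not built", call. = FALSE)
  sel <- seq.int(e$ptr[i], length.out = e$ptr[i + 1L] - e$ptr[i])
  tibble::tibble(nbr = e$nbr[sel], rel = e$rel[sel])
}

# filter map over ALL splits, both directions, keyed "h:r" -> tail index set
build_filter_map <- function(kg) {
  nr <- kg$n_rel_base
  all_h <- c(kg$train$h, kg$valid$h, kg$test$h, kg$valid$t, kg$test$t)
  all_r <- c(kg$train$r, kg$valid$r, kg$test$r, kg$valid$r + nr, kg$test$r + nr)
  all_t <- c(kg$train$t, kg$valid$t, kg$test$t, kg$valid$h, kg$test$h)
  key <- paste0(all_h, ":", all_r)
  fm <- new.env(parent = emptyenv(), size = length(unique(key)))
  sp <- split(all_t, key)
  for (k in names(sp)) assign(k, unique(sp[[k]]), envir = fm)
  fm
}

#' Known true tails for a query
#'
#' Looks up the filter map: every tail observed (in any split, after
#' reciprocal augmentation) for the query `(h, r, ?)`. Used by the filtered
#' ranking protocol to remove competing true candidates.
#'
#' @param kg An augmented `semlink_kg`.
#' @param h,r Head-entity and relation indices.
#' @return Integer vector of tail indices (possibly empty).
#' @export
kg_known_tails <- function(kg, h, r) {
  if (is.null(kg$filter_map)) stop("filter map not built", call. = FALSE)
  get0(paste0(h, ":", r), envir = kg$filter_map, ifnotfound = integer())
}

#' Summarise a knowledge graph
#'
#' @param kg A `semlink_kg`.
#' @return A one-row tibble: entity, relation (base, pre-augmentation) and
#'   per-split triple counts.
#' @export
kg_inspect <- function(kg) {
  n_train <- if (kg$reciprocal) nrow(kg$train) / 2L else nrow(kg$train)
  tibble::tibble(
    entities = length(kg$entities),
    relations = kg$n_rel_base,
    train = as.integer(n_train),
    valid = nrow(kg$valid),
    test = nrow(kg$test),
    triples = as.integer(n_train) + nrow(kg$valid) + nrow(kg$test)
  )
}

#' @export
print.semlink_kg <- function(x, ...) {
  info <- kg_inspect(x)
  cat("<semlink knowledge graph>\n")
  cat(sprintf("  entities: %d   relations: %d%s\n", info$entities, info$relations,
              if (x$reciprocal) " (+reciprocals)" else ""))
  cat(sprintf("  triples: train %d / valid %d / test %d\n",
              info$train, info$valid, info$test))
  invisible(x)
}

#' Write a knowledge graph's splits to a directory
#'
#' Writes `train.txt`, `valid.txt`, `test.txt` (label form; reciprocal
#' training triples are not written — they are derived data).
#'
#' @param kg A `semlink_kg`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
kg_write <- function(kg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- kg$train
  if (kg$reciprocal) tr <- tr[tr$r <= kg$n_rel_base, ]
  lab <- function(df) tibble::tibble(
    head = kg$entities[df$h], relation = kg$relations[df$r], tail = kg$entities[df$t]
  )
  write_triples(lab(tr), file.path(dir, "train.txt"))
  write_triples(lab(kg$valid), file.path(dir, "valid.txt"))
  write_triples(lab(kg$test), file.path(dir, "test.txt"))
  invisible(dir)
}
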