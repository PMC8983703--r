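# Descriptor index and ranked nearest-structure search.

#' Build a descriptor index over a collection of structure files
#'
#' Computes one descriptor per parseable file; per-file failures are
#' collected into a report rather than aborting the build (unless every
#' file fails). Entries are ordered by id for deterministic payloads.
#'
#' @param paths Character vector of structure files (PDB or mmCIF), or a
#'   directory (all `.pdb`/`.cif`/`.ent` files inside).
#' @param mode Atom subset for the surface.
#' @param order Descriptor order.
#' @param N Voxel grid size.
#' @param ... Further arguments to [compute_descriptor()].
#' @return A `zd_index`: list with `ids`, `mode`, `order`, `values`
#'   (D x n matrix), `vertices`, `faces`, `errors` (named character vector
#'   of per-file failures) and `meta`.
#' @export
build_index <- function(paths, mode = c("full_atom", "main_chain"),
                        order = 20, N = 200, ...) {
  mode <- match.arg(mode)
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE, ignore.case = TRUE)
  if (length(paths) == 0L) stop("no structure files to index")
  results <- lapply(paths, function(p) {
    tryCatch({
      s <- parse_structure(p)
      list(id = s$id, d = compute_descriptor(s, mode = mode, order = order,
                                             N = N, ...))
    }, error = function(e) list(id = tools::file_path_sans_ext(basename(p)),
                                error = conditionMessage(e)))
  })
  failed <- vapply(results, function(r) !is.null(r$error), logical(1))
  errors <- vapply(results[failed], `[[`, character(1), "error")
  names(errors) <- vapply(results[failed], `[[`, character(1), "id")
  ok <- results[!failed]
  if (length(ok) == 0L)
    stop("all files failed to index:\n",
         paste(sprintf("  %s: %s", names(errors), errors), collapse = "\n"))
  ord <- order(vapply(ok, `[[`, character(1), "id"))
  ok <- ok[ord]
  structure(list(
    ids = vapply(ok, `[[`, character(1), "id"),
    mode = mode, order = as.integer(order),
    values = vapply(ok, function(r) unname(r$d$values),
                    numeric(descriptor_length(order))),
    vertices = vapply(ok, function(r) r$d$mesh_vertices, integer(1)),
    faces = vapply(ok, function(r) r$d$mesh_faces, integer(1)),
    errors = errors,
    meta = list(tool = "zdsurf", version = as.character(utils::packageVersion("zdsurf")),
                grid_N = as.integer(N))),
    class = "zd_index")
}

#' Assemble an index from precomputed descriptors
#'
#' @param descriptors List of `zd_descriptor`s.
#' @param ids Entry identifiers (unique).
#' @param mode Shared source mode tag.
#' @return A `zd_index`.
#' @export
index_from_descriptors <- function(descriptors, ids,
                                   mode = c("full_atom", "main_chain")) {
  mode <- match.arg(mode)
  stopifnot(length(descriptors) == length(ids), !anyDuplicated(ids))
  orders <- vapply(descriptors, `[[`, integer(1), "order")
  if (length(unique(orders)) != 1) stop("descriptors have mixed orders")
  ord <- order(ids)
  structure(list(
    ids = ids[ord], mode = mode, order = orders[1],
    values = vapply(descriptors[ord], function(d) unname(d$values),
                    numeric(descriptor_length(orders[1]))),
    vertices = vapply(descriptors[ord], `[[`, integer(1), "mesh_vertices"),
    faces = vapply(descriptors[ord], `[[`, integer(1), "mesh_faces"),
    errors = character(0),
    meta = list(tool = "zdsurf",
                version = as.character(utils::packageVersion("zdsurf")))),
    class = "zd_index")
}

#' @export
print.zd_index <- function(x, ...) {
  cat("<zd_index> ", length(x$ids), " entries, order ", x$order,
      ", mode ", x$mode, "\n", sep = "")
  if (length(x$errors))
    cat("  (", length(x$errors), " files failed: ",
        paste(names(x$errors), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Ranked descriptor search
#'
#' Scores every index entry against the query — by direct descriptor
#' similarity (`zdzd`) or the siamese network probability (`nn`) — and
#' returns the top hits in non-increasing score order (ties broken by id).
#' The display distance shown beside each hit is `1 - score`, so a
#' same-fold-certain network hit displays a distance of 0.0.
#'
#' @param query A `zd_descriptor`.
#' @param index A `zd_index`.
#' @param method `"zdzd"` or `"nn"`.
#' @param top_k Number of hits returned (default 25; the full ranking when
#'   larger than the index).
#' @param params Trained `zd_nn_params` (required for `method = "nn"`).
#' @return A `zd_search_result`: data frame with `rank`, `id`, `score`,
#'   `distance`; attributes `method` and `query_id`.
#' @export
search_index <- function(query, index, method = c("zdzd", "nn"), top_k = 25,
                         params = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(query, "zd_descriptor"), inherits(index, "zd_index"))
  if (query$order != index$order)
    stop("query order ", query$order, " does not match index order ",
         index$order)
  if (!is.na(query$source_mode) && query$source_mode != index$mode)
    stop("query mode '", query$source_mode, "' does not match index mode '",
         index$mode, "'")
  n <- length(index$ids)
  if (n == 0L) stop("empty index")
  scores <- if (method == "zdzd") {
    d <- sqrt(colSums((index$values - descriptor_values(query))^2))
    1 / (1 + d)
  } else {
    if (is.null(params)) stop("method 'nn' requires trained network parameters")
    vapply(seq_len(n), function(i) {
      entry <- new_zd_descriptor(index$order, index$values[, i],
                                 index$mode, index$vertices[i],
                                 index$faces[i])
      nn_score(query, entry, params)$value
    }, numeric(1))
  }
  ord <- order(-scores, index$ids)
  take <- head(ord, top_k)
  res <- data.frame(rank = seq_along(take), id = index$ids[take],
                    score = scores[take], distance = 1 - scores[take],
                    stringsAsFactors = FALSE)
  attr(res, "method") <- method
  attr(res, "query_id") <- if (!is.null(attr(query, "id"))) attr(query, "id") else NA
  class(res) <- c("zd_search_result", class(res))
  res
}

#' Write / read a descriptor index
#'
#' Single-file JSON archive: a manifest (ids, mode, order, mesh counts,
#' metadata) plus the descriptor matrix at full precision.
#'
#' @param index A `zd_index`.
#' @param path File path (conventionally `.zsi`).
#' @return `path` invisibly (writer); a `zd_index` (reader).
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "zd_index"))
  jsonlite::write_json(
    list(manifest = list(ids = index$ids, mode = index$mode,
                         order = index$order, vertices = index$vertices,
                         faces = index$faces, meta = index$meta),
         values = as.numeric(index$values), dim = dim(index$values)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- x$manifest
  structure(list(ids = as.character(m$ids), mode = m$mode,
                 order = as.integer(m$order),
                 values = matrix(x$values, x$dim[1], x$dim[2]),
                 vertices = as.integer(m$vertices),
                 faces = as.integer(m$faces),
                 errors = character(0), meta = as.list(m$meta)),
            class = "zd_index")
}
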