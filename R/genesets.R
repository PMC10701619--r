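#' Construct a gene set
#'
#' A gene set is a named collection of unique gene identifiers, optionally
#' with a free-text description (the second column of the GMT format).
#' Identifiers are treated as opaque, case-sensitive strings; no alias
#' mapping is performed.
#'
#' @param name Set name (non-empty string).
#' @param members Character vector of gene identifiers; duplicates are
#'   removed with a warning.
#' @param description Free-text description.
#' @return An object of class `gene_set` with elements `name`,
#'   `description` and `members`.
#' @export
gene_set <- function(name, members, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set 'name' must be a single non-empty string")
  members <- as.character(members)
  if (length(members) == 0L)
    stop("gene set '", name, "' has no members")
  if (anyDuplicated(members)) {
    warning("gene set '", name, "' contains duplicate members; deduplicated")
    members <- unique(members)
  }
  structure(list(name = name, description = as.character(description)[1L],
                 members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "' (", length(x$members), " genes)\n", sep = "")
  invisible(x)
}

#' Construct a gene-set collection
#'
#' An ordered list of [gene_set] objects with unique names. Order is
#' preserved through file round-trips and through downstream scoring.
#'
#' @param sets A list of `gene_set` objects.
#' @return An object of class `gene_set_collection`: a list of gene sets
#'   named by their set names.
#' @export
gene_set_collection <- function(sets) {
  if (!is.list(sets)) stop("'sets' must be a list of gene_set objects")
  ok <- vapply(sets, inherits, logical(1L), what = "gene_set")
  if (length(sets) && !all(ok))
    stop("all elements of 'sets' must be gene_set objects")
  nms <- vapply(sets, `[[`, character(1L), "name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    stop("duplicate gene set name(s): ", paste(dup, collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "sets\n")
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i])
}

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format used by MSigDB: one set per line,
#' fields `name`, `description`, then one or more gene identifiers.
#' Duplicate genes within a line are deduplicated with a warning; duplicate
#' set names across lines are an error. Line order is preserved.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " (set '", fields[[1L]],
              "'): duplicate member genes deduplicated")
      members <- unique(members)
    }
    sets[[i]] <- gene_set(fields[[1L]], members, fields[[2L]])
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A [gene_set_collection].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
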