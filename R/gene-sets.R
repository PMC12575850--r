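#' Gene-set collections
#'
#' A `GeneSetCollection` is a named list of unique gene-identifier vectors
#' with a provenance label per set. Gene identity is the bare symbol string
#' and is case-sensitive by default; callers that need harmonization can
#' pass `case_fold = TRUE` or supply an alias table to
#' [assemble_multi_source()].
#'
#' @param sets Named list of character vectors (set name -> members).
#' @param provenance Character vector, one label per set; recycled from a
#'   single value.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, provenance = names(sets)) {
  assert_that(is.list(sets), "sets must be a list")
  if (length(sets) > 0) {
    assert_that(!is.null(names(sets)) && all(nzchar(names(sets))),
                "all sets must be named")
    assert_that(!anyDuplicated(names(sets)), "set names must be unique")
  }
  if (length(provenance) == 1L) provenance <- rep(provenance, length(sets))
  assert_that(length(provenance) == length(sets),
              "provenance must have one label per set")
  assert_that(!anyDuplicated(provenance) || length(sets) == 0,
              "duplicate provenance labels are rejected")
  sets <- lapply(sets, function(m) {
    m <- as.character(m)
    m <- m[nzchar(m)]
    unique(m)
  })
  structure(list(sets = sets, provenance = as.character(provenance)),
            class = "GeneSetCollection")
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
names.GeneSetCollection <- function(x) names(x$sets)

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection with %d set(s)\n", length(x)))
  for (i in seq_along(x$sets)) {
    cat(sprintf("  %s [%s]: %d genes\n", names(x$sets)[i],
                x$provenance[i], length(x$sets[[i]])))
  }
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then members, all tab-separated.
#' Blank member fields are dropped; duplicated members within a line are
#' removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_collection(stats::setNames(list(), character(0))))
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: expected name, description and members", i),
           call. = FALSE)
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in set '%s' (line %d) deduplicated",
                      fields[1], i))
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
  }
  gene_set_collection(sets)
}

#' Write a GMT gene-set file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions;
#'   defaults to the provenance labels.
#' @export
write_gmt <- function(collection, path, descriptions = collection$provenance) {
  assert_that(inherits(collection, "GeneSetCollection"),
              "collection must be a GeneSetCollection")
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], descriptions[i], collection$sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Path to a plain-text list, one gene symbol per line.
#' @param name Set name to use (defaults to the file name without extension).
#' @return A single-set [gene_set_collection()].
#' @export
read_gene_list <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  genes <- readLines(path, encoding = "UTF-8", warn = FALSE)
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  gene_set_collection(stats::setNames(list(unique(genes)), name))
}

#' Write a one-symbol-per-line gene list
#'
#' @param genes Character vector of gene symbols.
#' @param path Output path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path, useBytes = TRUE)
  invisible(path)
}

#' Assemble a multi-source gene universe
#'
#' Builds the mitochondria-related gene universe from several source lists
#' (e.g. exports of MitoCarta, MitoProteome and the AmiGO mitochondrion
#' annotation) by keeping genes present in at least `min_sources` of the
#' source sets and dropping genes backed by a single source only. The rule,
#' not any particular resulting count, is the contract: the universe size
#' depends on the database versions the user exports.
#'
#' @param sources A [gene_set_collection()] with one set per source.
#' @param min_sources Minimum number of distinct sources a gene must appear
#'   in; default 2.
#' @param case_fold If `TRUE`, symbols are compared case-insensitively
#'   (output is upper-cased).
#' @param alias_map Optional two-column data.frame (`alias`, `symbol`)
#'   applied to every source before counting, for identifier harmonization.
#' @return Character vector of retained genes, sorted lexicographically.
#' @examples
#' gs <- gene_set_collection(list(A = c("g1", "g2"), B = c("g2", "g3"),
#'                                C = "g3"))
#' assemble_multi_source(gs)  # "g2" "g3"
#' @export
assemble_multi_source <- function(sources, min_sources = 2L,
                                  case_fold = FALSE, alias_map = NULL) {
  assert_that(inherits(sources, "GeneSetCollection"),
              "sources must be a GeneSetCollection")
  assert_that(length(sources) >= 1, "at least one source set is required")
  assert_that(is_count(min_sources) && min_sources >= 1,
              "min_sources must be a positive integer")
  if (min_sources > length(sources)) {
    warning("min_sources exceeds the number of sources; returning empty list")
    return(character(0))
  }
  harmonize <- function(g) {
    if (!is.null(alias_map)) {
      idx <- match(g, alias_map$alias)
      g[!is.na(idx)] <- alias_map$symbol[idx[!is.na(idx)]]
    }
    if (case_fold) g <- toupper(g)
    unique(g)
  }
  counts <- table(unlist(lapply(sources$sets, harmonize), use.names = FALSE))
  sort(names(counts)[counts >= min_sources])
}
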