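# Gene sets: GMT I/O and the tibble convention used throughout.
#
# A collection of gene sets is a tibble with columns `set` (name),
# `description`, and `genes` (list-column of character vectors). Functions
# that take a single gene set accept a plain character vector.

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene symbols.
#' Within-set duplicates are removed with a logged count.
#'
#' @param path path to a GMT file.
#' @return tibble with columns `set`, `description`, `genes` (list-column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(set = character(), description = character(),
                  genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0)
    abort(paste0("GMT line ", short[1], " of ", path,
                 " has fewer than 3 tab-separated fields"))
  n_dup <- 0L
  genes <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    u <- unique(g)
    n_dup <<- n_dup + (length(g) - length(u))
    u
  })
  if (n_dup > 0)
    ct_log("read_gmt: removed ", n_dup, " duplicate gene entr",
           if (n_dup == 1) "y" else "ies")
  tibble(
    set = vapply(fields, `[[`, "", 1L),
    description = vapply(fields, `[[`, "", 2L),
    genes = genes
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets tibble as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(all(c("set", "description", "genes") %in% names(sets)))
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Resolve one gene set out of a collection or pass a character vector through.
as_gene_vector <- function(genes, sets = NULL) {
  if (is.character(genes) && length(genes) > 1 || is.null(sets))
    return(unique(as.character(genes)))
  if (is.character(genes) && genes %in% sets$set)
    return(sets$genes[[match(genes, sets$set)]])
  unique(as.character(genes))
}
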