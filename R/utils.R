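# shared helpers: locus ids, deterministic seeds, chromosome predicates

#' Format and parse locus identifiers
#'
#' Loci are labelled `"chrom:start-end"` with 0-based half-open coordinates,
#' the row-name convention of all methylation matrices in this package.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @return `locus_id()` a character vector; `parse_locus_id()` a
#'   `data.table` with columns `chrom`, `start`, `end`.
#' @export
locus_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' @rdname locus_id
#' @param id character vector of locus identifiers.
#' @export
parse_locus_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed locus id(s): ", paste(head(id[bad], 3), collapse = ", "))
  }
  data.table(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L))
  )
}

# deterministic 32-bit-safe integer seed from a string key, optionally
# offset by a user seed; used so per-segment fits are reproducible
seed_from_key <- function(key, offset = 0L) {
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483647
  as.integer((h + as.numeric(offset)) %% 2147483647)
}

is_autosome <- function(chrom) {
  grepl("^(chr)?[0-9]+$", chrom)
}

segment_key <- function(chrom, p1, p2, p3, p4) {
  sprintf("%s:%d-%d-%d-%d", chrom, p1, p2, p3, p4)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
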