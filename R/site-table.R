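#' Polarized biallelic site table
#'
#' The intermediate between a filtered VCF and the joint SFS: one row per
#' biallelic site with derived-allele and called-allele counts in each
#' population, plus the physical coordinates used for thinning.
#'
#' @param scaffold character vector of scaffold/contig ids.
#' @param position 1-based positions (as in VCF).
#' @param d1,d2 derived-allele counts per population.
#' @param c1,c2 called-allele counts per population (`<= 2 x` individuals).
#' @param ancestral,derived ancestral and derived alleles (single bases).
#' @return a data frame of class `site_table`.
#' @export
site_table <- function(scaffold, position, d1, c1, d2, c2,
                       ancestral = NA_character_, derived = NA_character_) {
  n <- length(scaffold)
  ancestral <- rep(as.character(ancestral), length.out = n)
  derived <- rep(as.character(derived), length.out = n)
  x <- data.frame(
    scaffold = as.character(scaffold),
    position = as.integer(position),
    d1 = as.integer(d1), c1 = as.integer(c1),
    d2 = as.integer(d2), c2 = as.integer(c2),
    ancestral = as.character(ancestral),
    derived = as.character(derived),
    stringsAsFactors = FALSE
  )
  validate_site_table(x)
  class(x) <- c("site_table", "data.frame")
  x
}

#' @rdname site_table
#' @param x object to validate.
#' @export
validate_site_table <- function(x) {
  req <- c("scaffold", "position", "d1", "c1", "d2", "c2")
  if (!all(req %in% names(x)))
    stop("site table must have columns ", paste(req, collapse = ", "))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(x$d1 < 0 | x$d2 < 0 | x$c1 < 0 | x$c2 < 0))
    stop("site table counts must be non-negative")
  if (any(x$d1 > x$c1 | x$d2 > x$c2))
    stop("derived counts must not exceed called-allele counts")
  if (all(c("ancestral", "derived") %in% names(x))) {
    both <- !is.na(x$ancestral) & !is.na(x$derived)
    if (any(both & x$ancestral == x$derived))
      stop("ancestral and derived alleles must differ")
  }
  invisible(x)
}

#' Read/write a site table as TSV
#' @param path file path.
#' @return `read_site_table`: a `site_table`; `write_site_table`: `path`.
#' @export
read_site_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  do.call(site_table, x[intersect(names(x), c(
    "scaffold", "position", "d1", "c1", "d2", "c2", "ancestral", "derived"))])
}

#' @rdname read_site_table
#' @param sites a `site_table`.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
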