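#' @title Two-population demographic models
#' @description
#' A demographic model describes the history of a population pair as an
#' ancestral population (optionally undergoing a size change before the
#' split) that splits into two populations evolving through 1-3 epochs,
#' ordered oldest to newest. Within an epoch, sizes (`nu1`, `nu2`, relative to
#' the reference size `N_ref`) and migration are constant. Migration per epoch
#' is absent, symmetric, or asymmetric; rates are in units of
#' `2 N_ref m` (population-scaled fraction of a population replaced by
#' migrants per generation). Models may additionally partition loci into two
#' classes: a "genomic island" class in which both migration rates are
#' multiplied by a factor `b` in [0, 1], holding a fraction `P_e` of loci in
#' epoch `e`. Time is in units of `2 N_ref` generations.
#'
#' Model identifiers follow a compact grammar:
#' `[a]e<k>_<codes>[_i]` where the optional leading `a` marks an ancestral
#' size change before the split, `k` in 1..3 is the number of post-split
#' epochs, `<codes>` is one character per epoch (oldest first) from
#' `n` (no migration), `s` (symmetric), `a` (asymmetric), and the optional
#' `_i` suffix enables the genomic-island mixture. Example: `ae2_ns_i` is an
#' ancestral size change, a split with an isolation epoch, then symmetric
#' secondary contact, with islands. The shipped catalog additionally contains
#' legacy names used in the gene-flow literature (e.g. `sc3ielsm1`, `iMi`,
#' `IMisc`); their structures are fixed aliases of grammar structures.
#' @name demography
NULL

.MIG_MODES <- c(n = "none", s = "sym", a = "asym")

.default_bounds <- function(name) {
  # log-uniform optimizer search ranges, chosen so their geometric midpoints
  # (the multi-start centres) sit at typical values: times ~0.3 x 2 N_ref
  # generations, sizes ~N_ref, scaled migration ~1, island fraction ~1%
  if (grepl("^T", name)) return(c(0.01, 10))
  if (grepl("^nu", name)) return(c(0.01, 100))
  if (grepl("^m", name)) return(c(0.02, 50))
  if (grepl("^P", name)) return(c(1e-4, 0.999))
  if (name == "b") return(c(1e-4, 1))
  stop("no default bounds for parameter ", name)
}

#' Construct a demographic model
#'
#' @param id model identifier (any string; grammar ids parse round-trip).
#' @param mig_modes character vector, one of `"none"`, `"sym"`, `"asym"` per
#'   post-split epoch, ordered oldest to newest (length 1-3).
#' @param islands logical; include the genomic-island migration mixture
#'   (island fraction `P_e` free in every epoch that has migration, plus one
#'   shared island migration factor `b`).
#' @param anc_change logical; include a pre-split ancestral size change
#'   (`nuA`, duration `TA`).
#' @param bounds optional named list of `c(lower, upper)` overriding default
#'   parameter bounds.
#' @return an object of class `demographic_model` with fields `id`,
#'   `n_epochs`, `mig_modes`, `islands`, `anc_change`, `params` (data frame
#'   `name`, `lower`, `upper`) and `k` (number of free parameters).
#' @export
demographic_model <- function(id, mig_modes, islands = FALSE,
                              anc_change = FALSE, bounds = list()) {
  mig_modes <- match.arg(mig_modes, c("none", "sym", "asym"),
                         several.ok = TRUE)
  k_ep <- length(mig_modes)
  if (k_ep < 1L || k_ep > 3L) stop("models must have 1-3 post-split epochs")
  if (islands && all(mig_modes == "none"))
    stop("island mixture requires migration in at least one epoch")
  nm <- character(0)
  if (anc_change) nm <- c(nm, "nuA", "TA")
  for (e in seq_len(k_ep)) {
    nm <- c(nm, sprintf("T%d", e), sprintf("nu1_%d", e), sprintf("nu2_%d", e))
    nm <- c(nm, switch(mig_modes[e],
                       none = character(0),
                       sym = sprintf("m%d", e),
                       asym = c(sprintf("m12_%d", e), sprintf("m21_%d", e))))
    if (islands && mig_modes[e] != "none") nm <- c(nm, sprintf("P%d", e))
  }
  if (islands) nm <- c(nm, "b")
  bd <- t(vapply(nm, function(p) {
    if (!is.null(bounds[[p]])) as.numeric(bounds[[p]]) else .default_bounds(p)
  }, numeric(2)))
  params <- data.frame(name = nm, lower = bd[, 1], upper = bd[, 2],
                       stringsAsFactors = FALSE)
  structure(list(id = id, n_epochs = k_ep, mig_modes = mig_modes,
                 islands = islands, anc_change = anc_change,
                 params = params, k = nrow(params)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("Demographic model '%s': %d epoch(s) [%s]%s%s, k = %d\n",
              x$id, x$n_epochs, paste(x$mig_modes, collapse = ", "),
              if (x$islands) ", genomic islands" else "",
              if (x$anc_change) ", ancestral size change" else "", x$k))
  invisible(x)
}

#' Parse a grammar model id
#'
#' Decodes `[a]e<k>_<codes>[_i]` (see [demography]) into a
#' [demographic_model] skeleton.
#'
#' @param id grammar id string.
#' @return a [demographic_model].
#' @examples
#' model_grammar_parse("ae2_ns_i")
#' @export
model_grammar_parse <- function(id) {
  m <- regmatches(id, regexec("^(a?)e([123])_([nsa]{1,3})(_i)?$", id))[[1]]
  if (length(m) == 0L || nchar(m[4]) != as.integer(m[3]))
    stop("cannot parse model id '", id, "'; grammar is [a]e<k>_<codes>[_i] ",
         "with k in 1..3 and <codes> k characters from ",
         "{n = no migration, s = symmetric, a = asymmetric}, ",
         "optional 'a' prefix = ancestral size change, ",
         "optional '_i' suffix = genomic-island mixture")
  demographic_model(
    id = id,
    mig_modes = unname(.MIG_MODES[strsplit(m[4], "")[[1]]]),
    islands = m[5] == "_i",
    anc_change = m[2] == "a"
  )
}

#' Render a model structure back to its grammar id
#' @param model a [demographic_model].
#' @return grammar id string.
#' @export
model_grammar_render <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  codes <- names(.MIG_MODES)[match(model$mig_modes, .MIG_MODES)]
  paste0(if (model$anc_change) "a" else "", "e", model$n_epochs, "_",
         paste(codes, collapse = ""), if (model$islands) "_i" else "")
}

# Paper-era legacy model names and their structures (aliases of grammar
# structures, reconstructed from the published figure descriptions):
# oldest-epoch code first.
.legacy_models <- function() {
  list(
    # 3 epochs: early low symmetric exchange, middle isolation, recent
    # asymmetric flow; islands. Two names circulate for this structure.
    sc3ielsm1 = list(codes = "sna", islands = TRUE, anc = FALSE),
    sc3imilm1 = list(codes = "sna", islands = TRUE, anc = FALSE),
    # isolation in the first historical epoch instead of the second
    sc3imlsm1 = list(codes = "nsa", islands = TRUE, anc = FALSE),
    # migration in all three epochs; no isolation epoch
    iMi       = list(codes = "sss", islands = TRUE, anc = FALSE),
    # 2 epochs: asymmetric then symmetric exchange; islands
    sc2ielsm2 = list(codes = "as", islands = TRUE, anc = FALSE),
    # as above but with a pre-divergence size-change episode
    sc12il    = list(codes = "ss", islands = TRUE, anc = TRUE),
    sc12imlsm2 = list(codes = "as", islands = TRUE, anc = TRUE),
    # 2 epochs: symmetric first then asymmetric; islands
    IMisc     = list(codes = "sa", islands = TRUE, anc = FALSE),
    # secondary contact: isolation then asymmetric / symmetric flow
    Sc2il     = list(codes = "na", islands = TRUE, anc = FALSE),
    Sc2ilsm   = list(codes = "ns", islands = TRUE, anc = FALSE),
    # gene flow in both epochs, asymmetric throughout
    Sc2i      = list(codes = "aa", islands = TRUE, anc = FALSE)
  )
}

.catalog_env <- new.env(parent = emptyenv())

#' The shipped catalog of 107 two-population models
#'
#' Enumerates the grammar space (1-2 post-split epochs with and without an
#' ancestral size change, 3 epochs without; every per-epoch migration
#' pattern; the island mixture wherever at least one epoch has migration;
#' the three-isolation-epoch structure `e3_nnn` omitted) plus the legacy
#' named models, for a catalog of exactly 107 entries.
#'
#' @return named list of [demographic_model] objects (length 107).
#' @export
catalog_list <- function() {
  if (!is.null(.catalog_env$catalog)) return(.catalog_env$catalog)
  models <- list()
  for (k in 1:3) {
    codes_all <- do.call(expand.grid, c(rep(list(c("n", "s", "a")), k),
                                        stringsAsFactors = FALSE))
    codes_all <- apply(codes_all[rev(seq_len(k))], 1L, paste, collapse = "")
    for (codes in sort(codes_all)) {
      if (k == 3L && codes == "nnn") next
      anc_opts <- if (k == 3L) FALSE else c(FALSE, TRUE)
      isl_opts <- if (grepl("^n+$", codes)) FALSE else c(FALSE, TRUE)
      for (anc in anc_opts) for (isl in isl_opts) {
        mdl <- demographic_model(
          id = paste0(if (anc) "a" else "", "e", k, "_", codes,
                      if (isl) "_i" else ""),
          mig_modes = unname(.MIG_MODES[strsplit(codes, "")[[1]]]),
          islands = isl, anc_change = anc)
        models[[mdl$id]] <- mdl
      }
    }
  }
  for (nm in names(.legacy_models())) {
    spec <- .legacy_models()[[nm]]
    models[[nm]] <- demographic_model(
      id = nm, mig_modes = unname(.MIG_MODES[strsplit(spec$codes, "")[[1]]]),
      islands = spec$islands, anc_change = spec$anc)
  }
  .catalog_env$catalog <- models
  models
}

#' Look up one catalog model by id
#' @param id model id present in [catalog_list()].
#' @return a [demographic_model].
#' @export
catalog_model <- function(id) {
  cat <- catalog_list()
  if (!id %in% names(cat))
    stop("model '", id, "' not found in the catalog (",
         length(cat), " models); see catalog_list()")
  cat[[id]]
}

#' Bind a parameter vector to a model
#'
#' Applies all structural constraints (symmetry ties, zero migration in
#' isolation epochs, island defaults) and returns fully specified epochs.
#'
#' @param model a [demographic_model].
#' @param values numeric vector of length `model$k`, in the order of
#'   `model$params$name` (a named vector is reordered by name).
#' @return list with elements `nuA`, `TA` (1 and 0 when no ancestral change)
#'   and `epochs`: a list (oldest first) of lists
#'   `T, nu1, nu2, m12, m21, P, b`.
#' @export
bind_parameters <- function(model, values) {
  stopifnot(inherits(model, "demographic_model"))
  nm <- model$params$name
  if (!is.null(names(values))) {
    if (!setequal(names(values), nm))
      stop("named values must match parameters: ", paste(nm, collapse = ", "))
    values <- values[nm]
  }
  if (length(values) != model$k)
    stop("expected ", model$k, " parameter values, got ", length(values))
  bad <- which(values < model$params$lower - 1e-12 |
                 values > model$params$upper + 1e-12)
  if (length(bad))
    stop("parameter out of bounds: ",
         paste(sprintf("%s = %g not in [%g, %g]", nm[bad], values[bad],
                       model$params$lower[bad], model$params$upper[bad]),
               collapse = "; "))
  v <- stats::setNames(as.numeric(values), nm)
  g <- function(p, default) if (p %in% nm) v[[p]] else default
  b <- g("b", 1)
  epochs <- lapply(seq_len(model$n_epochs), function(e) {
    mode <- model$mig_modes[e]
    m12 <- switch(mode, none = 0, sym = v[[sprintf("m%d", e)]],
                  asym = v[[sprintf("m12_%d", e)]])
    m21 <- switch(mode, none = 0, sym = v[[sprintf("m%d", e)]],
                  asym = v[[sprintf("m21_%d", e)]])
    list(T = v[[sprintf("T%d", e)]],
         nu1 = v[[sprintf("nu1_%d", e)]],
         nu2 = v[[sprintf("nu2_%d", e)]],
         m12 = m12, m21 = m21,
         P = if (model$islands && mode != "none") v[[sprintf("P%d", e)]] else 0,
         b = if (model$islands) b else 1)
  })
  list(nuA = g("nuA", 1), TA = g("TA", 0), epochs = epochs)
}

#' Write / read the model catalog as a YAML config
#'
#' One YAML document per model (`id`, epoch migration modes, island and
#' ancestral-change flags, parameter bounds). User-supplied custom model files
#' in the same format are accepted by [read_model_catalog()].
#'
#' @param path file path.
#' @param models named list of [demographic_model] (default: shipped catalog).
#' @return `write_model_catalog`: `path`; `read_model_catalog`: named list of
#'   [demographic_model].
#' @export
write_model_catalog <- function(path, models = catalog_list()) {
  docs <- vapply(models, function(m) {
    yaml::as.yaml(list(
      id = m$id,
      epochs = as.list(m$mig_modes),
      islands = m$islands,
      ancestral_size_change = m$anc_change,
      bounds = stats::setNames(
        lapply(seq_len(nrow(m$params)),
               function(i) c(m$params$lower[i], m$params$upper[i])),
        m$params$name)
    ))
  }, character(1))
  writeLines(paste0("---\n", paste(docs, collapse = "---\n")), path)
  invisible(path)
}

#' @rdname write_model_catalog
#' @export
read_model_catalog <- function(path) {
  txt <- readLines(path)
  bounds_list <- function(b) lapply(b, function(x) as.numeric(x))
  parse_doc <- function(s) {
    d <- yaml::yaml.load(s)
    demographic_model(id = d$id, mig_modes = unlist(d$epochs),
                      islands = isTRUE(d$islands),
                      anc_change = isTRUE(d$ancestral_size_change),
                      bounds = bounds_list(d$bounds))
  }
  pieces <- strsplit(paste(txt, collapse = "\n"), "\n---\n|^---\n")[[1]]
  pieces <- pieces[nzchar(trimws(pieces))]
  models <- lapply(pieces, parse_doc)
  stats::setNames(models, vapply(models, `[[`, character(1), "id"))
}
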