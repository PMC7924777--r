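#' @include AllClasses.R AllGenerics.R
NULL

.OPEN <- "0"

.normToken <- function(tok) {
  tok <- trimws(tok)
  if (tok %in% c("0", "∅", "Ø")) .OPEN else tok
}

#' Parse a reaction diagram
#'
#' Reads a reaction in diagram notation, e.g. `"A + 0 -> A + A"` (binary
#' fission), `"A -> 0"` (death), `"0 -> A"` (immigration) or
#' `"F + 0 -> 0 + F"` (migration).  Both `"0"` and the empty-set symbol
#' denote an open site, and both `"->"` and the arrow glyph are accepted.
#' The reaction type (on-site vs pairwise) is inferred from the arity, and
#' products are positional: the first product occupies the center site, the
#' second the neighbor site.
#'
#' For pairwise reactions the rate constant is per ordered (center,
#' neighbor) pair.  In particular, for a symmetric reaction such as
#' `"A + A -> B + 0"` each unordered adjacent A-A pair contributes twice
#' the rate constant to the total propensity, because either particle can
#' act as the center.
#'
#' @param diagram reaction diagram string.
#' @param rate nonnegative mass-action rate constant.
#' @param name optional reaction label (defaults to the diagram).
#' @param species optional character vector of declared species; when
#'   given, unknown tokens raise an error here rather than at model
#'   validation.
#' @return a [Reaction-class].
#' @examples
#' parseReaction("A + 0 -> A + A", 1.0)   # pairwise binary fission
#' parseReaction("A -> 0", 0.5)           # on-site death
#' @export
parseReaction <- function(diagram, rate, name = NULL, species = NULL) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate < 0)
    stop("rate must be a single nonnegative number")
  sides <- strsplit(gsub("→", "->", diagram), "->", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stop(sprintf("malformed reaction diagram (expected one '->'): '%s'", diagram))
  lhs <- vapply(strsplit(sides[1], "+", fixed = TRUE)[[1]], .normToken, "")
  rhs <- vapply(strsplit(sides[2], "+", fixed = TRUE)[[1]], .normToken, "")
  if (any(!nzchar(c(lhs, rhs))))
    stop(sprintf("empty species token in '%s'", diagram))
  if (length(lhs) != length(rhs))
    stop(sprintf("reactant and product arity differ in '%s'", diagram))
  if (length(lhs) > 2)
    stop(sprintf("more than two reactants in '%s': reduce higher-order reactions to pairwise steps via intermediate complexes", diagram))
  if (length(lhs) == 1 && lhs[1] == .OPEN && rhs[1] == .OPEN)
    stop("null reaction '0 -> 0'")
  if (!is.null(species)) {
    unknown <- setdiff(c(lhs, rhs), c(.OPEN, species))
    if (length(unknown))
      stop(sprintf("unknown species token(s): %s", paste(unknown, collapse = ", ")))
  }
  rtype <- if (length(lhs) == 2) "pairwise" else "on_site"
  new("Reaction",
      name = if (is.null(name)) formatDiagram(lhs, rhs) else name,
      rtype = rtype,
      center = unname(lhs[1]),
      nbr = if (rtype == "pairwise") unname(lhs[2]) else NA_character_,
      prodCenter = unname(rhs[1]),
      prodNbr = if (rtype == "pairwise") unname(rhs[2]) else NA_character_,
      rate = as.numeric(rate))
}

formatDiagram <- function(lhs, rhs)
  paste(paste(lhs, collapse = " + "), "->", paste(rhs, collapse = " + "))

#' Canonical diagram string of a reaction
#'
#' Inverse of [parseReaction()]: `parseReaction(formatReaction(r), r@rate)`
#' reproduces `r` up to the name.
#'
#' @param reaction a [Reaction-class].
#' @return character diagram using `"0"` for open sites and `"->"`.
#' @export
formatReaction <- function(reaction) {
  stopifnot(is(reaction, "Reaction"))
  if (reaction@rtype == "on_site")
    formatDiagram(reaction@center, reaction@prodCenter)
  else
    formatDiagram(c(reaction@center, reaction@nbr),
                  c(reaction@prodCenter, reaction@prodNbr))
}

#' Assemble an interacting-particle-system model
#'
#' @param species character vector of species names (open sites `"0"` are
#'   not a species and must not be listed).
#' @param reactions list of [Reaction-class] objects, or a named numeric
#'   vector/list mapping diagram strings to rate constants.
#' @param check if `TRUE` (default), [validateModel()] is run and any
#'   diagnostics raise an error.
#' @return an [IPSModel-class].
#' @examples
#' m <- ipsModel(c("F", "R"), list(
#'   parseReaction("F + R -> F + F", 0.5, "predation"),
#'   parseReaction("R + 0 -> R + R", 0.3, "reproduction")))
#' nSpecies(m)
#' @export
ipsModel <- function(species, reactions, check = TRUE) {
  if (is.numeric(reactions) || (is.list(reactions) && !is.null(names(reactions)) &&
                                all(vapply(reactions, is.numeric, TRUE))))
    reactions <- mapply(parseReaction, names(reactions), unlist(reactions),
                        SIMPLIFY = FALSE, USE.NAMES = FALSE)
  m <- new("IPSModel", species = as.character(species), reactions = reactions)
  if (check) {
    diag <- validateModel(m)
    if (length(diag))
      stop("invalid model:\n  ", paste(diag, collapse = "\n  "))
  }
  m
}

#' Validate a model
#'
#' Checks the structural invariants of a model and returns diagnostics
#' rather than raising errors: unique species names, the reserved open-site
#' token, declared species in every reaction, no null/no-op reactions, and
#' nonnegative rates.
#'
#' @param model an [IPSModel-class].
#' @return character vector of diagnostics; empty if the model is valid.
#' @export
validateModel <- function(model) {
  diags <- character(0)
  sp <- model@species
  if (anyDuplicated(sp))
    diags <- c(diags, sprintf("duplicate species name(s): %s",
                              paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  if (.OPEN %in% sp || any(sp %in% c("∅", "Ø")))
    diags <- c(diags, "the open site '0' is not a species and cannot be declared")
  if (!length(model@reactions))
    diags <- c(diags, "model has no reactions")
  for (i in seq_along(model@reactions)) {
    r <- model@reactions[[i]]
    if (!is(r, "Reaction")) {
      diags <- c(diags, sprintf("reaction %d is not a Reaction object", i))
      next
    }
    lab <- sprintf("reaction %d (%s)", i, r@name)
    toks <- c(r@center, r@nbr, r@prodCenter, r@prodNbr)
    toks <- toks[!is.na(toks)]
    unknown <- setdiff(toks, c(.OPEN, sp))
    if (length(unknown))
      diags <- c(diags, sprintf("%s: unknown species %s", lab,
                                paste(unknown, collapse = ", ")))
    if (r@rtype == "pairwise") {
      if (r@center == .OPEN && r@nbr == .OPEN &&
          r@prodCenter == .OPEN && r@prodNbr == .OPEN) {
        diags <- c(diags, sprintf("%s: null reaction (all slots open)", lab))
      } else if (identical(c(r@center, r@nbr), c(r@prodCenter, r@prodNbr))) {
        diags <- c(diags, sprintf("%s: no-op reaction (products equal reactants)", lab))
      }
    } else {
      if (r@center == r@prodCenter)
        diags <- c(diags, sprintf("%s: no-op reaction (product equals reactant)", lab))
    }
    if (is.na(r@rate) || r@rate < 0)
      diags <- c(diags, sprintf("%s: negative or missing rate", lab))
  }
  diags
}

#' @describeIn ipsModel species names.
#' @param x an [IPSModel-class].
#' @export
setMethod("speciesNames", "IPSModel", function(x) x@species)

#' @rdname ipsModel
#' @export
setMethod("nSpecies", "IPSModel", function(x) length(x@species))

#' @rdname ipsModel
#' @export
setMethod("reactionList", "IPSModel", function(x) x@reactions)

setMethod("show", "Reaction", function(object) {
  cat(sprintf("Reaction '%s' [%s]: %s, rate = %g\n", object@name,
              object@rtype, formatReaction(object), object@rate))
})

setMethod("show", "IPSModel", function(object) {
  cat(sprintf("IPSModel: %d species (%s), %d reactions\n",
              nSpecies(object), paste(object@species, collapse = ", "),
              length(object@reactions)))
  for (r in object@reactions)
    cat(sprintf("  %-22s %-9s %s  rate %g\n", r@name, r@rtype,
                formatReaction(r), r@rate))
})

# species name -> integer code (0 = open)
.speciesCode <- function(tokens, species) {
  code <- match(tokens, species)
  code[which(tokens == .OPEN)] <- 0L
  if (anyNA(code[!is.na(tokens)]))
    stop("reaction references undeclared species")
  as.integer(code)
}
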