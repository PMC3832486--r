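# Plain-text model description language (MDL).
#
# Grammar (one statement per line, '#' starts a comment):
#   species line:   <name> = <integer>        ("$" prefix marks a fixed,
#                                              buffered species)
#   parameter line: <name> : <real>
#   reaction line:  <rname>: <reactants> > <products>, <rate>
#     reactants/products: "+"-separated "coef*name" terms ("name" for
#     coefficient 1), or "$pool" for an empty side; "$name" references a
#     fixed species. <rate> is a bare constant or a parameter name (mass
#     action), or an arithmetic expression over species and parameters.

#' Parse a model description
#'
#' Reads the package's plain-text model description language (see Details)
#' and returns a validated [ssa_model()]. Errors carry the offending line
#' number.
#'
#' @details One statement per line; `#` starts a comment. Species are
#' declared as `name = integer` (prefix `$` for fixed/buffered species),
#' parameters as `name : real`, and reactions as
#' `Rname: reactants > products, rate` where each side is a `+`-separated
#' list of `coef*name` terms or `$pool` for an empty side. A rate that is a
#' bare number or a single parameter name is mass action; anything else is
#' an expression rate law evaluated on current copy numbers.
#'
#' @param text Model description: a single string (possibly multi-line) or a
#'   character vector of lines.
#' @param path Alternatively, a file to read.
#' @return An `ssa_model`.
#' @seealso [write_mdl()] for the inverse.
#' @export
parse_mdl <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("either text or path must be given")
    text <- readLines(path, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  species <- list(); reactions <- list(); parameters <- numeric(0)
  perr <- function(i, ...) stop("MDL line ", i, ": ", ..., call. = FALSE)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") next
    if (grepl("^\\$?[A-Za-z][A-Za-z0-9_]*\\s*=", ln)) {
      # species
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2L) perr(i, "malformed species line")
      nm <- trimws(parts[[1]])
      fixed <- startsWith(nm, "$")
      if (fixed) nm <- substring(nm, 2L)
      val <- suppressWarnings(as.numeric(trimws(parts[[2]])))
      if (is.na(val)) perr(i, "initial amount of '", nm, "' is not a number")
      if (val < 0) perr(i, "negative initial amount for '", nm, "'")
      if (val != round(val))
        perr(i, "initial amount of '", nm, "' is not an integer")
      species[[length(species) + 1L]] <- ssa_species(nm, val, fixed = fixed)
    } else if (grepl("^[A-Za-z][A-Za-z0-9_]*\\s*:", ln)) {
      rest <- sub("^[A-Za-z][A-Za-z0-9_]*\\s*:", "", ln)
      nm <- trimws(sub(":.*$", "", ln))
      if (grepl(">", rest, fixed = TRUE)) {
        reactions[[length(reactions) + 1L]] <-
          tryCatch(parse_reaction_line(nm, rest),
                   error = function(e) perr(i, conditionMessage(e)))
      } else {
        val <- suppressWarnings(as.numeric(trimws(rest)))
        if (is.na(val)) perr(i, "parameter '", nm, "' value is not a number")
        parameters[[nm]] <- val
      }
    } else {
      perr(i, "unrecognized statement: '", ln, "'")
    }
  }
  if (length(species) == 0L && length(reactions) == 0L)
    stop("MDL input declares no species and no reactions", call. = FALSE)
  # resolve parameter-name mass-action rates; leave true expressions alone
  sn <- vapply(species, `[[`, "", "name")
  for (j in seq_along(reactions)) {
    law <- reactions[[j]]$law
    if (law$type == "expression" &&
        grepl("^[A-Za-z][A-Za-z0-9_]*$", law$expr)) {
      id <- law$expr
      if (id %in% names(parameters)) {
        reactions[[j]]$law <- list(type = "mass_action",
                                   c = parameters[[id]], c_name = id)
      } else if (!(id %in% sn)) {
        stop("reaction '", reactions[[j]]$name, "': undefined identifier '",
             id, "'", call. = FALSE)
      }
    }
  }
  ssa_model(species, reactions, parameters)
}

parse_side <- function(txt) {
  txt <- trimws(txt)
  if (txt == "$pool" || txt == "") return(integer(0))
  terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  out <- integer(0)
  for (tm in terms) {
    coef <- 1L
    if (grepl("^[0-9]+\\s*\\*", tm)) {
      coef <- as.integer(sub("\\s*\\*.*$", "", tm))
      tm <- trimws(sub("^[0-9]+\\s*\\*", "", tm))
    }
    if (startsWith(tm, "$")) tm <- substring(tm, 2L)
    if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", tm))
      stop("malformed stoichiometry term '", tm, "'")
    out[[tm]] <- (if (tm %in% names(out)) out[[tm]] else 0L) + coef
  }
  out
}

parse_reaction_line <- function(name, rest) {
  # rest is " reactants > products, rate"; split at the last top-level comma
  chars <- strsplit(rest, "")[[1]]
  depth <- 0L; cut <- NA_integer_
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    else if (chars[k] == ")") depth <- depth - 1L
    else if (chars[k] == "," && depth == 0L) cut <- k
  }
  if (is.na(cut)) stop("reaction line is missing the ', rate' part")
  eqn <- substr(rest, 1L, cut - 1L)
  rate_txt <- trimws(substr(rest, cut + 1L, nchar(rest)))
  sides <- strsplit(eqn, ">", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("reaction must have exactly one '>'")
  reactants <- parse_side(sides[[1]])
  products <- parse_side(sides[[2]])
  num <- suppressWarnings(as.numeric(rate_txt))
  rate <- if (!is.na(num)) num else rate_txt
  ssa_reaction(name, reactants, products, rate)
}

#' Write a model description
#'
#' Serializes a model to the plain-text model description language such that
#' [parse_mdl()] reproduces a semantically identical model (same species
#' order, stoichiometry, rate laws, parameters).
#'
#' @param model An `ssa_model`.
#' @param path Optional file to write to.
#' @return The model description as a single string (invisibly when `path`
#'   is given).
#' @export
write_mdl <- function(model, path = NULL) {
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  side <- function(v) {
    if (length(v) == 0L) return("$pool")
    paste(ifelse(v > 1L, paste0(v, "*", names(v)), names(v)), collapse = " + ")
  }
  fixed <- vapply(model$species, `[[`, FALSE, "fixed")
  out <- character(0)
  for (s in model$species)
    out <- c(out, paste0(if (s$fixed) "$" else "", s$name, " = ", s$initial))
  for (p in names(model$parameters))
    out <- c(out, paste0(p, " : ", fmt(model$parameters[[p]])))
  sn <- species_names(model)
  mark <- function(v) {
    if (length(v) == 0L) return(v)
    names(v) <- ifelse(fixed[match(names(v), sn)], paste0("$", names(v)),
                       names(v))
    v
  }
  for (r in model$reactions) {
    rate <- if (r$law$type == "mass_action") {
      if (!is.null(r$law$c_name) && !is.na(r$law$c_name)) r$law$c_name
      else fmt(r$law$c)
    } else r$law$expr
    out <- c(out, paste0(r$name, ": ", side(mark(r$reactants)), " > ",
                         side(mark(r$products)), ", ", rate))
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}
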