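# Model definition: species, reactions, rate laws, and the restricted
# arithmetic expression interpreter used for non-mass-action propensities.

# opcode table shared with src/solvers.cpp (keep in sync)
.OP_CONST <- 1L; .OP_SPEC <- 2L; .OP_ADD <- 3L; .OP_SUB <- 4L; .OP_MUL <- 5L
.OP_DIV <- 6L; .OP_POW <- 7L; .OP_NEG <- 8L; .OP_MIN <- 9L; .OP_MAX <- 10L
.OP_EXP <- 11L; .OP_LOG <- 12L

#' Construct a species record
#'
#' @param name Species identifier (letters, digits, `_`, starting with a
#'   letter).
#' @param initial Non-negative integer initial copy number.
#' @param fixed If `TRUE` the species is buffered/clamped: it contributes to
#'   propensities but is never changed by reaction firings (the `$` prefix in
#'   the model description language).
#' @param partition If `TRUE` (default) the species is binomially partitioned
#'   at cell division; set to `FALSE` for gene-like species that every
#'   daughter keeps.
#' @return A list of class `ssa_species`.
#' @export
ssa_species <- function(name, initial, fixed = FALSE, partition = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", name))
    stop("invalid species name: ", name)
  if (length(initial) != 1L || is.na(initial) || initial < 0 ||
      initial != round(initial))
    stop("initial copy number of '", name,
         "' must be a non-negative integer, got ", initial)
  structure(list(name = name, initial = as.integer(round(initial)),
                 fixed = isTRUE(fixed), partition = isTRUE(partition)),
            class = "ssa_species")
}

#' Construct a reaction record
#'
#' A reaction has reactant and product multiplicity maps and a rate law.
#' Mass-action rate laws carry a single rate constant `c` (units: time^-1 for
#' zero- and first-order channels, per-pair time^-1 for bimolecular ones);
#' the propensity is then `c` times the number of distinct reactant
#' combinations, using the combinatorial convention `c * n * (n - 1) / 2` for
#' dimerization. Expression rate laws are arithmetic expressions over species
#' names and parameters, evaluated on the current copy numbers.
#'
#' @param name Reaction identifier.
#' @param reactants,products Named integer vectors mapping species name to
#'   multiplicity; `NULL` or empty for a source/sink side.
#' @param rate Either a single number (mass-action constant), or a single
#'   string holding an arithmetic expression (operators `+ - * / ^`,
#'   parentheses, `min`, `max`, `exp`, `log`).
#' @return A list of class `ssa_reaction`.
#' @export
ssa_reaction <- function(name, reactants = NULL, products = NULL, rate) {
  stopifnot(is.character(name), length(name) == 1L)
  norm_side <- function(x, what) {
    if (is.null(x) || length(x) == 0L) return(integer(0))
    if (is.null(names(x)) || any(names(x) == ""))
      stop("reaction '", name, "': ", what, " must be a named vector")
    if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
      stop("reaction '", name, "': ", what, " multiplicities must be ",
           "non-negative integers")
    x <- x[x > 0]
    stats::setNames(as.integer(round(x)), names(x))
  }
  reactants <- norm_side(reactants, "reactants")
  products <- norm_side(products, "products")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction '", name, "': reactants and products both empty")
  if (is.numeric(rate) && length(rate) == 1L) {
    law <- list(type = "mass_action", c = as.numeric(rate), c_name = NA_character_)
  } else if (is.character(rate) && length(rate) == 1L) {
    law <- list(type = "expression", expr = rate)
  } else stop("reaction '", name, "': rate must be a number or a string")
  structure(list(name = name, reactants = reactants, products = products,
                 law = law), class = "ssa_reaction")
}

#' Construct a reaction-network model
#'
#' @param species List of [ssa_species()] records; their order fixes the
#'   state-vector index convention.
#' @param reactions List of [ssa_reaction()] records.
#' @param parameters Named numeric vector of rate parameters usable in
#'   expression rate laws.
#' @return A validated list of class `ssa_model`.
#' @export
ssa_model <- function(species, reactions, parameters = numeric(0)) {
  if (inherits(species, "ssa_species")) species <- list(species)
  if (inherits(reactions, "ssa_reaction")) reactions <- list(reactions)
  if (length(parameters) && (is.null(names(parameters)) ||
                             any(names(parameters) == "")))
    stop("parameters must be a named numeric vector")
  m <- structure(list(species = species, reactions = reactions,
                      parameters = parameters), class = "ssa_model")
  validate_model(m)
  m
}

#' @export
print.ssa_model <- function(x, ...) {
  cat("<ssa_model> ", length(x$species), " species, ",
      length(x$reactions), " reactions, ",
      length(x$parameters), " parameters\n", sep = "")
  for (s in x$species)
    cat("  ", if (s$fixed) "$" else "", s$name, " = ", s$initial, "\n", sep = "")
  for (r in x$reactions) {
    side <- function(v) if (length(v) == 0L) "$pool" else
      paste(ifelse(v > 1L, paste0(v, "*", names(v)), names(v)), collapse = " + ")
    rate <- if (r$law$type == "mass_action") format(r$law$c) else r$law$expr
    cat("  ", r$name, ": ", side(r$reactants), " > ", side(r$products),
        ", ", rate, "\n", sep = "")
  }
  invisible(x)
}

species_names <- function(model) vapply(model$species, `[[`, "", "name")
reaction_names <- function(model) vapply(model$reactions, `[[`, "", "name")

#' Initial state vector of a model
#'
#' @param model An `ssa_model`.
#' @return Named integer vector of initial copy numbers, in species order.
#' @export
initial_state <- function(model) {
  stats::setNames(vapply(model$species, `[[`, 0L, "initial"),
                  species_names(model))
}

#' Net stoichiometry matrix
#'
#' @param model An `ssa_model`.
#' @return Integer matrix, species x reactions, of net copy-number changes
#'   (products minus reactants); rows of fixed (`$`-prefixed) species are
#'   zero since buffered species are never updated.
#' @export
stoichiometry <- function(model) {
  sn <- species_names(model)
  nu <- matrix(0L, length(sn), length(model$reactions),
               dimnames = list(sn, reaction_names(model)))
  fixed <- vapply(model$species, `[[`, FALSE, "fixed")
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (s in names(r$reactants)) nu[s, j] <- nu[s, j] - r$reactants[[s]]
    for (s in names(r$products)) nu[s, j] <- nu[s, j] + r$products[[s]]
  }
  nu[fixed, ] <- 0L
  nu
}

reactant_matrix <- function(model) {
  sn <- species_names(model)
  mr <- matrix(0L, length(sn), length(model$reactions),
               dimnames = list(sn, reaction_names(model)))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (s in names(r$reactants)) mr[s, j] <- mr[s, j] + r$reactants[[s]]
  }
  mr
}

validate_model <- function(model) {
  sn <- species_names(model)
  if (anyDuplicated(sn)) stop("duplicate species names: ",
                              paste(sn[duplicated(sn)], collapse = ", "))
  rn <- reaction_names(model)
  if (anyDuplicated(rn)) stop("duplicate reaction names: ",
                              paste(rn[duplicated(rn)], collapse = ", "))
  known <- c(sn, names(model$parameters))
  for (r in model$reactions) {
    refs <- c(names(r$reactants), names(r$products))
    bad <- setdiff(refs, sn)
    if (length(bad))
      stop("reaction '", r$name, "': undefined identifier '", bad[[1]], "'")
    if (r$law$type == "expression") {
      ids <- expr_identifiers(r$law$expr)
      bad <- setdiff(ids, known)
      if (length(bad))
        stop("reaction '", r$name, "': undefined identifier '", bad[[1]],
             "' in rate law")
      compile_expr(r$law$expr, sn, model$parameters)  # catch syntax errors
    }
  }
  invisible(TRUE)
}

## ---- restricted arithmetic expression interpreter -------------------------

expr_tokenize <- function(expr) {
  pat <- "([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)|([A-Za-z][A-Za-z0-9_]*)|(\\*\\*)|([-+*/^(),])"
  m <- gregexpr(pat, expr, perl = TRUE)[[1]]
  if (m[1] == -1) stop("rate expression is empty or unparseable: '", expr, "'")
  toks <- regmatches(expr, gregexpr(pat, expr, perl = TRUE))[[1]]
  covered <- sum(attr(m, "match.length"))
  residual <- gsub("[[:space:]]", "", expr)
  if (nchar(residual) != sum(nchar(toks)))
    stop("invalid character in rate expression: '", expr, "'")
  toks
}

expr_identifiers <- function(expr) {
  toks <- expr_tokenize(expr)
  ids <- toks[grepl("^[A-Za-z]", toks)]
  setdiff(unique(ids), c("min", "max", "exp", "log"))
}

# shunting-yard to RPN; returns list(code = integer opcodes, arg = numeric)
compile_expr <- function(expr, species, parameters) {
  toks <- expr_tokenize(expr)
  toks[toks == "**"] <- "^"
  code <- integer(0); arg <- numeric(0)
  emit <- function(op, a = 0) {
    code[[length(code) + 1L]] <<- op
    arg[[length(arg) + 1L]] <<- a
  }
  prec <- c("+" = 2, "-" = 2, "*" = 3, "/" = 3, "^" = 4, "u-" = 5)
  right <- c("^", "u-")
  opstack <- character(0)
  pop_op <- function(tok) {
    switch(tok,
           "+" = emit(.OP_ADD), "-" = emit(.OP_SUB), "*" = emit(.OP_MUL),
           "/" = emit(.OP_DIV), "^" = emit(.OP_POW), "u-" = emit(.OP_NEG),
           "min" = emit(.OP_MIN), "max" = emit(.OP_MAX),
           "exp" = emit(.OP_EXP), "log" = emit(.OP_LOG),
           stop("internal: bad operator ", tok))
  }
  expect_operand <- TRUE
  for (tok in toks) {
    if (grepl("^[0-9.]", tok)) {
      emit(.OP_CONST, as.numeric(tok)); expect_operand <- FALSE
    } else if (tok %in% c("min", "max", "exp", "log")) {
      opstack <- c(opstack, tok); expect_operand <- TRUE
    } else if (grepl("^[A-Za-z]", tok)) {
      i <- match(tok, species)
      if (!is.na(i)) emit(.OP_SPEC, i)
      else if (tok %in% names(parameters)) emit(.OP_CONST, parameters[[tok]])
      else stop("undefined identifier '", tok, "' in expression '", expr, "'")
      expect_operand <- FALSE
    } else if (tok == "(") {
      opstack <- c(opstack, tok); expect_operand <- TRUE
    } else if (tok == ",") {
      while (length(opstack) && opstack[length(opstack)] != "(") {
        pop_op(opstack[length(opstack)])
        opstack <- opstack[-length(opstack)]
      }
      if (!length(opstack)) stop("misplaced ',' in expression '", expr, "'")
      expect_operand <- TRUE
    } else if (tok == ")") {
      while (length(opstack) && opstack[length(opstack)] != "(") {
        pop_op(opstack[length(opstack)])
        opstack <- opstack[-length(opstack)]
      }
      if (!length(opstack)) stop("unbalanced ')' in expression '", expr, "'")
      opstack <- opstack[-length(opstack)]
      # a function call directly below the parenthesis
      if (length(opstack) &&
          opstack[length(opstack)] %in% c("min", "max", "exp", "log")) {
        pop_op(opstack[length(opstack)])
        opstack <- opstack[-length(opstack)]
      }
      expect_operand <- FALSE
    } else if (tok %in% c("+", "-", "*", "/", "^")) {
      if (expect_operand) {
        if (tok == "-") { opstack <- c(opstack, "u-"); next }
        if (tok == "+") next
        stop("misplaced operator '", tok, "' in expression '", expr, "'")
      }
      while (length(opstack)) {
        top <- opstack[length(opstack)]
        if (top == "(" || top %in% c("min", "max", "exp", "log")) break
        if (prec[[top]] > prec[[tok]] ||
            (prec[[top]] == prec[[tok]] && !(tok %in% right))) {
          pop_op(top); opstack <- opstack[-length(opstack)]
        } else break
      }
      opstack <- c(opstack, tok); expect_operand <- TRUE
    } else stop("unexpected token '", tok, "' in expression '", expr, "'")
  }
  while (length(opstack)) {
    top <- opstack[length(opstack)]
    if (top == "(") stop("unbalanced '(' in expression '", expr, "'")
    pop_op(top); opstack <- opstack[-length(opstack)]
  }
  # sanity: simulate stack depth
  depth <- 0L
  for (k in seq_along(code)) {
    op <- code[[k]]
    if (op %in% c(.OP_CONST, .OP_SPEC)) depth <- depth + 1L
    else if (op %in% c(.OP_NEG, .OP_EXP, .OP_LOG)) {
      if (depth < 1L) stop("malformed expression '", expr, "'")
    } else {
      if (depth < 2L) stop("malformed expression '", expr, "'")
      depth <- depth - 1L
    }
  }
  if (depth != 1L) stop("malformed expression '", expr, "'")
  list(code = code, arg = arg)
}

# vectorized RPN evaluation; states is a matrix (rows = states)
rpn_eval <- function(prog, states) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  stack <- vector("list", length(prog$code))
  top <- 0L
  for (k in seq_along(prog$code)) {
    op <- prog$code[[k]]; a <- prog$arg[[k]]
    if (op == .OP_CONST) { top <- top + 1L; stack[[top]] <- rep(a, nrow(states)) }
    else if (op == .OP_SPEC) { top <- top + 1L; stack[[top]] <- states[, a] }
    else if (op == .OP_NEG) stack[[top]] <- -stack[[top]]
    else if (op == .OP_EXP) stack[[top]] <- exp(stack[[top]])
    else if (op == .OP_LOG) stack[[top]] <- log(stack[[top]])
    else {
      b <- stack[[top]]; top <- top - 1L; a1 <- stack[[top]]
      stack[[top]] <- switch(as.character(op),
                             "3" = a1 + b, "4" = a1 - b, "5" = a1 * b,
                             "6" = a1 / b, "7" = a1 ^ b,
                             "9" = pmin(a1, b), "10" = pmax(a1, b))
    }
  }
  stack[[1L]]
}

# compiled form consumed by the C++ solvers and the CME builder
compile_model <- function(model) {
  sn <- species_names(model)
  prog <- vector("list", length(model$reactions))
  law_type <- integer(length(model$reactions))
  cvec <- rep(NA_real_, length(model$reactions))
  for (j in seq_along(model$reactions)) {
    law <- model$reactions[[j]]$law
    if (law$type == "mass_action") {
      law_type[j] <- 0L
      cvec[j] <- law$c
      prog[[j]] <- list(code = integer(0), arg = numeric(0))
    } else {
      law_type[j] <- 1L
      prog[[j]] <- compile_expr(law$expr, sn, model$parameters)
    }
  }
  list(nu_net = stoichiometry(model),
       nu_reac = reactant_matrix(model),
       law_type = law_type, c = cvec,
       code = lapply(prog, `[[`, "code"),
       arg = lapply(prog, `[[`, "arg"),
       species = sn, reactions = reaction_names(model))
}

## ---- propensities ---------------------------------------------------------

mass_action_factor <- function(n, m) {
  # number of distinct reactant combinations: prod_{k=0}^{m-1}(n-k) / m!
  out <- rep(1, length(n))
  for (k in seq_len(max(m, 0)) - 1L) out <- out * pmax(n - k, 0)
  out / factorial(m)
}

#' Reaction propensities at a state
#'
#' Evaluates every reaction's propensity at one or more copy-number states.
#' Mass-action channels use the combinatorial convention (zero order: `c`;
#' `A`: `c*nA`; `A+B`: `c*nA*nB`; `2A`: `c*nA*(nA-1)/2`). Expression rate
#' laws are evaluated by the package's restricted arithmetic interpreter; a
#' negative value is clipped to zero with a warning.
#'
#' @param model An `ssa_model`.
#' @param state Named or ordered integer vector (or matrix, states in rows)
#'   of copy numbers.
#' @return Numeric vector (or matrix) of propensities, one per reaction.
#' @export
propensities <- function(model, state = initial_state(model)) {
  cm <- compile_model(model)
  one <- is.null(dim(state))
  S <- if (one) matrix(as.numeric(state), nrow = 1L,
                       dimnames = list(NULL, names(state)))
       else { Sm <- as.matrix(state); storage.mode(Sm) <- "double"; Sm }
  if (!is.null(colnames(S)) || (one && !is.null(names(state)))) {
    nm <- if (one) names(state) else colnames(S)
    if (!is.null(nm)) {
      if (!setequal(nm, cm$species))
        stop("state names do not match model species")
      S <- S[, match(cm$species, nm), drop = FALSE]
    }
  }
  if (any(S < 0)) stop("state must be non-negative")
  A <- matrix(0, nrow(S), length(model$reactions),
              dimnames = list(NULL, cm$reactions))
  clipped <- FALSE
  for (j in seq_along(model$reactions)) {
    if (cm$law_type[j] == 0L) {
      a <- rep(cm$c[j], nrow(S))
      mr <- cm$nu_reac[, j]
      for (i in which(mr > 0L)) a <- a * mass_action_factor(S[, i], mr[i])
    } else {
      a <- rpn_eval(list(code = cm$code[[j]], arg = cm$arg[[j]]), S)
      if (any(!is.finite(a)))
        stop("rate law of reaction '", cm$reactions[j],
             "' evaluated to a non-finite value")
      if (any(a < 0)) { clipped <- TRUE; a <- pmax(a, 0) }
    }
    A[, j] <- a
  }
  if (clipped)
    warning("negative expression propensity clipped to 0")
  if (one) A[1L, ] else A
}

#' Propensity of a single reaction channel
#'
#' @param model An `ssa_model`.
#' @param reaction Reaction name or index.
#' @param state Copy-number state vector (defaults to the initial state).
#' @return A single non-negative number.
#' @export
compute_propensity <- function(model, reaction, state = initial_state(model)) {
  j <- if (is.character(reaction)) match(reaction, reaction_names(model))
       else as.integer(reaction)
  if (is.na(j) || j < 1L || j > length(model$reactions))
    stop("unknown reaction: ", reaction)
  unname(propensities(model, state)[j])
}

#' Set the division-partitioning flag of species
#'
#' @param model An `ssa_model`.
#' @param species Character vector of species names.
#' @param partition Logical; `FALSE` marks gene-like species that are not
#'   binomially partitioned at division (the tracked daughter keeps the
#'   copies).
#' @return The modified model.
#' @export
set_partitioning <- function(model, species, partition) {
  sn <- species_names(model)
  bad <- setdiff(species, sn)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  for (i in match(species, sn)) model$species[[i]]$partition <- isTRUE(partition)
  model
}
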