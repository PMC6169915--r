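## CellML-subset adapter (optional import/export path).
##
## Supported subset: a flat list of components whose <variable> elements
## carry name/initial_value and whose <math> blocks contain content-MathML
## equations of the forms `var = expr` and `d(var)/d(time) = expr`, with
## operators plus/minus/times/divide/power, functions exp/ln/log/abs, and
## numeric <cn>/<ci> leaves.  Units, imports and encapsulation are ignored.
## This is sufficient to round-trip the bundled toy model and to load
## comparably structured single-cell models; it is not a general CellML
## implementation.

#' @keywords internal
#' @noRd
.expr_to_mathml <- function(e) {
  if (is.numeric(e)) return(sprintf("<cn>%s</cn>", format(e, digits = 17)))
  if (is.name(e)) return(sprintf("<ci>%s</ci>", as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- lapply(as.list(e)[-1], .expr_to_mathml)
    if (op == "(") return(args[[1]])
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power", exp = "exp", log = "ln",
                  abs = "abs",
                  stop("cellml export: unsupported operator '", op, "'"))
    return(sprintf("<apply><%s/>%s</apply>", tag,
                   paste(unlist(args), collapse = "")))
  }
  stop("cellml export: unsupported expression component")
}

#' @keywords internal
#' @noRd
.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm != "apply")
    stop("cellml import: unsupported MathML node <", nm, ">")
  ch <- xml2::xml_children(node)
  op <- xml2::xml_name(ch[[1]])
  args <- lapply(ch[-1], .mathml_to_expr)
  bin <- function(sym) {
    if (length(args) == 1 && sym == "-") return(call("-", args[[1]]))
    Reduce(function(a, b) call(sym, a, b), args)
  }
  switch(op,
         plus = bin("+"), minus = bin("-"), times = bin("*"),
         divide = bin("/"), power = bin("^"),
         exp = call("exp", args[[1]]), ln = call("log", args[[1]]),
         log = call("log", args[[1]]), abs = call("abs", args[[1]]),
         stop("cellml import: unsupported MathML operator <", op, ">"))
}

#' @keywords internal
#' @noRd
.toy_equations <- function() {
  assigns <- list(
    EK = quote(26.71 * log(Ko / Ki)),
    dinf = quote(1 / (1 + exp(-(V + 10) / 6))),
    finf = quote(1 / (1 + exp((V + 25) / 6))),
    ninf = quote(1 / (1 + exp(-(V - 5) / 9))),
    k1inf = quote(1 / (1 + exp((V - EK - 12) / 12))),
    ICa = quote(G_Ca * dinf * f * (V - E_Ca)),
    IK = quote(G_K * n * (V - EK)),
    IK1 = quote(G_K1 * k1inf * (V - EK)),
    INaK = quote(G_NaK * (Ko / (Ko + 1.5)) / (1 + exp(-(V + 80) / 25))),
    IKp = quote(G_Kp * (V - EK) / (1 + exp((7.488 - V) / 5.98))),
    IClbk = quote(G_Clbk * (V - E_Clbk)),
    IKtot = quote(IK + IK1 + IKp - 2 * INaK + Istim))
  odes <- list(
    V = quote(-(ICa + IK + IK1 + INaK + IKp + IClbk + Istim)),
    f = quote((finf - f) / tau_f),
    n = quote((ninf - n) / tau_n),
    Cai = quote(-k_conv * ICa - (Cai - Ca_rest) / tau_Ca),
    Ki = quote(-kappa_K * IKtot),
    qK = quote(IKtot))
  list(assigns = assigns, odes = odes)
}

#' Export the toy model as a CellML document
#'
#' Serializes the toy model equations and parameter values into a flat
#' CellML 1.1 document (content MathML, single component) that
#' [load_cellml_model()] reads back; the round trip reproduces the
#' right-hand side to near machine precision.
#'
#' @param model a toy `ionic_model` (from [toy_ventricular_model()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cellml <- function(model, path) {
  stopifnot(inherits(model, "ionic_model"))
  if (model$name != "toy_ventricular")
    stop("write_cellml: only the toy model has a stored equation set")
  eq <- .toy_equations()
  pars <- model$params[!names(model$params) %in% c("stim_amp", "stim_dur")]
  vars <- c(
    "    <variable name=\"time\"/>",
    sprintf("    <variable name=\"%s\" initial_value=\"%s\"/>",
            names(model$state0), format(model$state0, digits = 17)),
    sprintf("    <variable name=\"%s\" initial_value=\"%s\"/>",
            names(pars), format(pars, digits = 17)),
    "    <variable name=\"Istim\" initial_value=\"0\"/>",
    sprintf("    <variable name=\"%s\"/>", names(eq$assigns)))
  math <- c(
    vapply(names(eq$assigns), function(v)
      sprintf("      <apply><eq/><ci>%s</ci>%s</apply>", v,
              .expr_to_mathml(eq$assigns[[v]])), character(1)),
    vapply(names(eq$odes), function(v)
      sprintf(paste0("      <apply><eq/><apply><diff/><bvar><ci>time</ci>",
                     "</bvar><ci>%s</ci></apply>%s</apply>"), v,
              .expr_to_mathml(eq$odes[[v]])), character(1)))
  doc <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<model name=\"toy_ventricular\" xmlns=\"http://www.cellml.org/cellml/1.1#\">",
    "  <component name=\"main\">",
    vars,
    "    <math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    math,
    "    </math>",
    "  </component>",
    "</model>")
  writeLines(doc, path)
  invisible(path)
}

#' Load an ionic model from a CellML-subset document
#'
#' Parses variables and content-MathML equations (see the file header of
#' this adapter for the supported subset), classifies variables into
#' states (those with a time derivative), algebraic assignments and
#' parameters (those with an `initial_value` and no defining equation), and
#' assembles an `ionic_model` whose right-hand side evaluates the equations
#' in dependency order.
#'
#' @param path CellML file path.
#' @param current_map named character vector mapping [currents_record()]
#'   slots to model variable names (e.g. `c(IKr = "IK", INaK = "INaK")`);
#'   required for any potassium-budget computation on the loaded model.
#'   Mapped variables must exist in the document.
#' @param stim_var name of the stimulus-current variable; during pacing the
#'   protocol drivers override it with the configured pulse.
#' @return an `ionic_model` (pure-R right-hand side).
#' @export
load_cellml_model <- function(path, current_map = NULL, stim_var = "Istim") {
  if (!file.exists(path)) stop("load_cellml_model: no such file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  vars <- xml2::xml_find_all(doc, ".//variable")
  vnames <- xml2::xml_attr(vars, "name")
  vinit <- suppressWarnings(as.numeric(xml2::xml_attr(vars, "initial_value")))
  names(vinit) <- vnames

  eqs <- xml2::xml_find_all(doc, ".//math/apply")
  odes <- list(); assigns <- list()
  time_var <- "time"
  for (node in eqs) {
    ch <- xml2::xml_children(node)
    if (xml2::xml_name(ch[[1]]) != "eq")
      stop("load_cellml_model: top-level MathML element is not an equation")
    lhs <- ch[[2]]; rhs <- .mathml_to_expr(ch[[3]])
    if (xml2::xml_name(lhs) == "apply" &&
        xml2::xml_name(xml2::xml_children(lhs)[[1]]) == "diff") {
      lch <- xml2::xml_children(lhs)
      time_var <- trimws(xml2::xml_text(xml2::xml_find_first(lch[[2]], ".//ci")))
      sv <- trimws(xml2::xml_text(lch[[3]]))
      odes[[sv]] <- rhs
    } else if (xml2::xml_name(lhs) == "ci") {
      assigns[[trimws(xml2::xml_text(lhs))]] <- rhs
    } else stop("load_cellml_model: unsupported equation left-hand side")
  }
  if (!length(odes)) stop("load_cellml_model: no rate equations found")

  states <- names(odes)
  state0 <- vinit[states]
  if (any(is.na(state0))) {
    warning("load_cellml_model: states without initial_value set to 0: ",
            paste(states[is.na(state0)], collapse = ", "))
    state0[is.na(state0)] <- 0
  }
  pnames <- setdiff(vnames[!is.na(vinit)], c(states, names(assigns), time_var))
  params <- vinit[pnames]

  known_names <- c(states, pnames, names(assigns), time_var)
  if (!is.null(current_map)) {
    missing <- setdiff(unname(current_map), known_names)
    if (length(missing))
      stop("load_cellml_model: current map names variables not in the model: ",
           paste(missing, collapse = ", "))
  }

  ## order assignments so every reference is defined before use
  order <- character()
  avail <- c(states, pnames, time_var, stim_var)
  pending <- names(assigns)
  while (length(pending)) {
    ready <- pending[vapply(pending, function(v)
      all(all.vars(assigns[[v]]) %in% avail), logical(1))]
    if (!length(ready))
      stop("load_cellml_model: circular or unresolved assignments: ",
           paste(pending, collapse = ", "))
    order <- c(order, ready)
    avail <- c(avail, ready)
    pending <- setdiff(pending, ready)
  }

  rhs <- function(t, state, params, stim = 0) {
    env <- new.env(parent = baseenv())
    for (v in names(params)) assign(v, params[[v]], envir = env)
    for (v in states) assign(v, state[[v]], envir = env)
    assign(time_var, t, envir = env)
    assign(stim_var, stim, envir = env)
    for (v in order) assign(v, eval(assigns[[v]], env), envir = env)
    deriv <- vapply(states, function(v) eval(odes[[v]], env), numeric(1))
    cr <- if (!is.null(current_map)) {
      vals <- vapply(unname(current_map), function(v) get(v, envir = env),
                     numeric(1))
      currents_record(c(setNames(vals, names(current_map)),
                        if (!"Istim" %in% names(current_map))
                          c(Istim = stim)))
    } else currents_record(Istim = stim)
    list(deriv = deriv, currents = cr)
  }

  nm <- xml2::xml_attr(doc, "name")
  structure(list(
    name = if (is.na(nm)) basename(path) else nm,
    state0 = state0,
    params = c(params, stim_amp = -40, stim_dur = 2),
    conductances = grep("^G_", pnames, value = TRUE),
    Ko_param = if ("Ko" %in% pnames) "Ko" else NULL,
    atol = setNames(ifelse(names(state0) == "V", 1e-6, 1e-9),
                    names(state0)),
    rtol = 1e-6,
    rhs = rhs, currents_fun = NULL, compiled = NULL,
    current_map = current_map, stim_var = stim_var),
    class = "ionic_model")
}

#' Add intracellular-potassium dynamics to a model
#'
#' Replaces a constant intracellular-potassium parameter by a state obeying
#' `dKi/dt = -kappa * I_K,tot`, where the total potassium current is
#' computed from the model's current map (Eq-18 bookkeeping: all potassium
#' currents, minus twice the sodium-potassium pump, plus the stimulus).
#' The sodium–potassium pump slot `INaK` must be mapped.
#'
#' @param model an `ionic_model` whose right-hand side returns a currents
#'   record (e.g. from [load_cellml_model()] with a `current_map`).
#' @param ki_var name of the constant potassium parameter to promote.
#' @param kappa conversion factor `Cmem/(Vmyo*Frdy)` in
#'   mM/((pA/pF)*ms); alternatively give the three constants.
#' @param Cmem,Vmyo,Frdy constants used when `kappa` is NULL.
#' @return the augmented model, with one more state than before.
#' @export
add_ki_dynamics <- function(model, ki_var = "Ki", kappa = NULL,
                            Cmem = NULL, Vmyo = NULL, Frdy = NULL) {
  stopifnot(inherits(model, "ionic_model"))
  if (is.null(kappa)) {
    if (is.null(Cmem) || is.null(Vmyo) || is.null(Frdy))
      stop("add_ki_dynamics: give 'kappa' or all of Cmem, Vmyo, Frdy")
    kappa <- Cmem / (Vmyo * Frdy)
  }
  if (ki_var %in% names(model$state0))
    stop("add_ki_dynamics: '", ki_var, "' is already a state")
  if (!ki_var %in% names(model$params))
    stop("add_ki_dynamics: no parameter '", ki_var, "' in the model")
  if (is.null(model$current_map) || !"INaK" %in% names(model$current_map))
    stop("add_ki_dynamics: current map must include 'INaK' ",
         "(the potassium budget needs the sodium-potassium pump)")
  base_rhs <- model$rhs
  base_states <- names(model$state0)
  ki0 <- model$params[[ki_var]]
  model$state0 <- c(model$state0, setNames(ki0, ki_var))
  model$params <- model$params[names(model$params) != ki_var]
  model$atol <- c(model$atol, setNames(1e-9, ki_var))
  model$rhs <- function(t, state, params, stim = 0) {
    params2 <- c(params, setNames(state[[ki_var]], ki_var))
    r <- base_rhs(t, state[base_states], params2, stim = stim)
    IKtot <- ik_tot(r$currents)
    r$deriv <- c(r$deriv, setNames(-kappa * IKtot, ki_var))
    r
  }
  model
}
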