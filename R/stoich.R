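#' @name stoich
#' @title Leaching stoichiometry: species, reactions, balances and budgets
#'
#' @description
#' Pyrite biooxidation supplies the two lixiviants of the co-leaching
#' process: sulfuric acid (from direct oxidative pyrite dissolution) and
#' ferric iron (regenerated microbially from ferrous iron). These tools
#' parse the charged-species equations of that chemistry, verify element and
#' charge balance, and convert molar throughputs into acid/iron/oxygen
#' budgets.
NULL

# Recognised element symbols; "Me" is a placeholder divalent base metal so
# the generic metal-leaching equations can be balance-checked symbolically.
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb",
  "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "W", "Re", "Os", "Ir", "Pt",
  "Au", "Hg", "Tl", "Pb", "Bi", "U", "Me")

#' Parse a chemical species token
#'
#' Accepts an elemental formula with an optional trailing charge, e.g.
#' `"FeS2"`, `"SO4-2"`, `"H+1"`, `"Fe+3"`, `"H2SO4"`. `"Me"` is a
#' placeholder divalent metal usable in generic equations.
#'
#' @param token Species string.
#' @return A list of class `chem_species`: `formula` (element -> count),
#'   `charge` (integer), `label` (the input token).
#' @examples
#' parse_species("SO4-2")
#' @export
parse_species <- function(token) {
  token <- trimws(token)
  m <- regmatches(token, regexec("^([A-Za-z0-9]+?)([+-][0-9]+)?$", token))[[1]]
  if (length(m) == 0L || m[2] == "") {
    stop("cannot parse species '", token, "'", call. = FALSE)
  }
  formula_str <- m[2]
  charge <- if (m[3] == "") 0L else as.integer(m[3])

  pieces <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula_str)[[1]]
  parts <- regmatches(formula_str, gregexpr("([A-Z][a-z]?)([0-9]*)",
                                            formula_str))[[1]]
  if (sum(nchar(parts)) != nchar(formula_str) || length(parts) == 0L) {
    stop("cannot parse formula '", formula_str, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    if (!(el %in% ELEMENT_SYMBOLS)) {
      stop("unknown element symbol '", el, "' in species '", token, "'",
           call. = FALSE)
    }
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (n == "") 1L else as.integer(n)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  structure(list(formula = counts, charge = charge, label = token),
            class = "chem_species")
}

#' Parse a chemical reaction from plain text
#'
#' Equation syntax: terms separated by `" + "`, sides by `"->"`, each term an
#' optional (possibly fractional) coefficient followed by a species token:
#' `"FeS2 + 14 Fe+3 + 8 H2O -> 15 Fe+2 + 2 SO4-2 + 16 H+1"`.
#'
#' @param text Equation string.
#' @return A list of class `chem_reaction` with `reactants` and `products`,
#'   each a list of `coef` / `species` pairs, and `text` (the input).
#' @export
parse_reaction <- function(text) {
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    stop("reaction must contain exactly one '->': ", text, call. = FALSE)
  }
  parse_side <- function(s) {
    terms <- strsplit(trimws(s), "\\s\\+\\s")[[1]]
    lapply(terms, function(term) {
      bits <- strsplit(trimws(term), "\\s+")[[1]]
      if (length(bits) == 2L) {
        coef <- suppressWarnings(as.numeric(bits[1]))
        if (is.na(coef) || coef <= 0) {
          stop("bad coefficient in term '", term, "'", call. = FALSE)
        }
        list(coef = coef, species = parse_species(bits[2]))
      } else if (length(bits) == 1L) {
        list(coef = 1, species = parse_species(bits[1]))
      } else {
        stop("cannot parse term '", term, "'", call. = FALSE)
      }
    })
  }
  structure(list(reactants = parse_side(sides[1]),
                 products = parse_side(sides[2]),
                 text = trimws(text)),
            class = "chem_reaction")
}

#' @export
print.chem_reaction <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

side_totals <- function(side) {
  elements <- numeric(0)
  charge <- 0
  for (term in side) {
    f <- term$species$formula
    for (el in names(f)) {
      elements[el] <- (if (el %in% names(elements)) elements[[el]] else 0) +
        term$coef * f[[el]]
    }
    charge <- charge + term$coef * term$species$charge
  }
  list(elements = elements, charge = charge)
}

#' Check element and charge balance of a reaction
#'
#' @param rxn A `chem_reaction` (or equation string, parsed on the fly).
#' @return A list with `elements` (named residual vector, reactant minus
#'   product totals per element), `charge` (residual), and `balanced`
#'   (`TRUE` iff every residual is zero to 1e-9).
#' @examples
#' check_balance("FeS2 + 14 Fe+3 + 8 H2O -> 15 Fe+2 + 2 SO4-2 + 16 H+1")
#' @export
check_balance <- function(rxn) {
  if (is.character(rxn)) rxn <- parse_reaction(rxn)
  lhs <- side_totals(rxn$reactants)
  rhs <- side_totals(rxn$products)
  els <- union(names(lhs$elements), names(rhs$elements))
  resid <- vapply(els, function(el) {
    l <- if (el %in% names(lhs$elements)) lhs$elements[[el]] else 0
    r <- if (el %in% names(rhs$elements)) rhs$elements[[el]] else 0
    l - r
  }, numeric(1))
  charge_resid <- lhs$charge - rhs$charge
  list(elements = resid, charge = charge_resid,
       balanced = all(abs(resid) < 1e-9) && abs(charge_resid) < 1e-9)
}

#' Substitute the placeholder metal in a reaction
#'
#' Replaces the divalent placeholder `Me` by a concrete metal symbol (Cu,
#' Ni, Zn, ...), so generic equations can be checked per metal.
#'
#' @param rxn A `chem_reaction` or equation string.
#' @param metal Element symbol to substitute, e.g. `"Cu"`.
#' @return A `chem_reaction`.
#' @examples
#' instantiate_metal("Me + 2 Fe+3 -> Me+2 + 2 Fe+2", "Cu")
#' @export
instantiate_metal <- function(rxn, metal) {
  text <- if (is.character(rxn)) rxn else rxn$text
  if (!(metal %in% setdiff(ELEMENT_SYMBOLS, "Me"))) {
    stop("unknown metal symbol '", metal, "'", call. = FALSE)
  }
  parse_reaction(gsub("Me", metal, text, fixed = TRUE))
}

#' The pyrite/PCB leaching reaction set
#'
#' The six reactions of the co-leaching chemistry, read from the packaged
#' plain-text fixture: direct oxidative pyrite dissolution
#' (`pyrite_direct_O2`), microbial ferrous-iron oxidation
#' (`iron_oxidation`), ferric pyrite leaching (`pyrite_ferric`), generic
#' base-metal leaching by ferric iron (`metal_ferric`) and by acid plus
#' oxygen (`metal_acid_O2`), and metallic-nickel dissolution in sulfuric
#' acid (`nickel_acid`).
#'
#' @param metal If non-`NULL`, substitute the placeholder `Me` by this
#'   element symbol in the generic metal reactions.
#' @return Named list of `chem_reaction` objects.
#' @examples
#' rxns <- bioleach_reactions(metal = "Cu")
#' all(vapply(rxns, function(r) check_balance(r)$balanced, logical(1)))
#' @export
bioleach_reactions <- function(metal = NULL) {
  path <- system.file("extdata", "leaching_reactions.txt",
                      package = "cobioleach", mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("each reaction line must be 'name<TAB>equation'", call. = FALSE)
  }
  rxns <- lapply(parts, function(p) parse_reaction(p[2L]))
  names(rxns) <- vapply(parts, `[[`, character(1), 1L)
  if (!is.null(metal)) {
    rxns <- lapply(rxns, function(r) {
      if (grepl("Me", r$text, fixed = TRUE)) instantiate_metal(r, metal)
      else r
    })
  }
  rxns
}

#' Acid and iron budget of pyrite oxidation
#'
#' Converts a molar pyrite throughput into the stoichiometric budget of the
#' chosen oxidation pathway. `direct_O2` (oxygen pathway): per mol FeS2,
#' 2 mol H+ and 1 mol Fe2+ produced, 3.5 mol O2 consumed. `ferric`
#' (ferric-leach pathway): per mol FeS2, 16 mol H+ and 15 mol Fe2+ produced,
#' 14 mol Fe3+ consumed.
#'
#' @param mol_FeS2 Moles of pyrite oxidised (>= 0).
#' @param pathway `"direct_O2"` or `"ferric"`.
#' @return Named numeric vector: `h_plus_produced`, `fe2_produced`,
#'   `fe3_consumed`, `o2_consumed` (mol). Linear in `mol_FeS2`.
#' @examples
#' pyrite_budget(1, "ferric")
#' @export
pyrite_budget <- function(mol_FeS2, pathway = c("direct_O2", "ferric")) {
  pathway <- match.arg(pathway)
  if (any(mol_FeS2 < 0)) stop("'mol_FeS2' must be >= 0", call. = FALSE)
  per_mol <- switch(pathway,
    direct_O2 = c(h_plus_produced = 2, fe2_produced = 1,
                  fe3_consumed = 0, o2_consumed = 3.5),
    ferric = c(h_plus_produced = 16, fe2_produced = 15,
               fe3_consumed = 14, o2_consumed = 0))
  per_mol * mol_FeS2
}

#' Lixiviant demand of base-metal leaching
#'
#' Stoichiometric demand per mole of metallic metal leached. `ferric`:
#' 2 mol Fe3+ per mol Me0. `acid_O2`: 1 mol H2SO4 and 0.5 mol O2 per mol
#' Me0. `nickel_acid`: the same acid/oxygen ratios for metallic nickel.
#'
#' @param mol_metal Moles of metal leached (>= 0).
#' @param route `"ferric"`, `"acid_O2"` or `"nickel_acid"`.
#' @return Named numeric vector: `fe3_required`, `h2so4_required`,
#'   `o2_required` (mol). Linear in `mol_metal`.
#' @examples
#' metal_leach_demand(1, "ferric")       # 2 mol Fe3+
#' metal_leach_demand(1, "nickel_acid")  # 1 mol H2SO4, 0.5 mol O2
#' @export
metal_leach_demand <- function(mol_metal,
                               route = c("ferric", "acid_O2", "nickel_acid")) {
  route <- match.arg(route)
  if (any(mol_metal < 0)) stop("'mol_metal' must be >= 0", call. = FALSE)
  per_mol <- switch(route,
    ferric = c(fe3_required = 2, h2so4_required = 0, o2_required = 0),
    acid_O2 = c(fe3_required = 0, h2so4_required = 1, o2_required = 0.5),
    nickel_acid = c(fe3_required = 0, h2so4_required = 1, o2_required = 0.5))
  per_mol * mol_metal
}

#' Control-corrected metal leach yield
#'
#' The fraction of a metal's mass in the fed PCB dust mobilised into the
#' liquid phase, corrected for the metal the control reactor mobilises from
#' the tailings alone:
#' \deqn{Y_m = \frac{m_{LE} - m_{LC}}{X_i \, V_{total} \, \omega} \times 100\%}
#' `m_le` and `m_lc` are grams of metal in the whole liquid phase of the
#' experimental and control reactors (concentration times liquid volume,
#' computed upstream). Values outside [0, 100] are reported unclipped but
#' flagged: they diagnose control mismatch or sampling error, not a physical
#' yield.
#'
#' @param m_le Metal mass in the experimental reactor liquid phase (g).
#' @param m_lc Metal mass in the control reactor liquid phase (g).
#' @param xi In-reactor PCB dust concentration (g/L), e.g. from
#'   [run_schedule()].
#' @param v_total Reactor working volume (L).
#' @param omega Mass fraction of the target metal in the PCB dust (0-1),
#'   e.g. from [pcb_composition()].
#' @return A list with `yield_pct` and `in_range` (`TRUE` iff 0-100).
#' @examples
#' leach_yield(m_le = 0.091, m_lc = 0, xi = 5, v_total = 1,
#'             omega = pcb_composition()[["Cu"]])  # 70%
#' @export
leach_yield <- function(m_le, m_lc, xi, v_total, omega) {
  if (m_le < 0 || m_lc < 0) stop("masses must be >= 0", call. = FALSE)
  if (omega <= 0 || omega >= 1) stop("'omega' must be in (0, 1)", call. = FALSE)
  denom <- xi * v_total * omega
  if (denom <= 0) {
    stop("zero or negative denominator: xi * v_total * omega must be > 0",
         call. = FALSE)
  }
  y <- (m_le - m_lc) / denom * 100
  list(yield_pct = y, in_range = y >= 0 && y <= 100)
}

#' Elemental composition of the PCB dust fraction
#'
#' Mass fractions (g/g) of the quantified elements in the shredder-dust PCB
#' sample used in the co-leaching experiments (ICP-AES). Elements reported
#' only as upper bounds (Pd, Rh, Pt) are omitted.
#'
#' @return Named numeric vector of mass fractions.
#' @examples
#' pcb_composition()[["Cu"]]  # 0.026
#' @export
pcb_composition <- function() {
  c(Si = 0.10, Fe = 0.08, Cu = 0.026, Al = 0.020, Pb = 0.017, Zn = 0.010,
    Ni = 0.005, Sn = 0.005, Cd = 0.0004, Ag = 0.00026, Au = 0.00001)
}
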