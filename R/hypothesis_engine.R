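#' Default library of known autophagy modulators
#'
#' Fixed (target, direction) assignments for the agents whose step on the
#' autophagic flux is established: rapamycin (RAP) and Torin-2 (TOR) relieve
#' mTOR inhibition of AP formation; starvation (STV) both stimulates
#' formation and enhances fusion with lysosomes; wortmannin (WRT) and
#' Spautin-1 (SPA) block nucleation (formation); hydroxychloroquine (HCQ)
#' and bafilomycin (BAF) block AP-lysosome fusion (conversion). Strengths
#' are left free (`NA`) and are estimated from data.
#'
#' @return A [modifier_table()] with 8 assignments over 7 agents.
#' @export
agent_library <- function() {
  modifier_table(
    agent     = c("RAP", "TOR", "STV", "STV", "WRT", "SPA", "HCQ", "BAF"),
    target    = c("formation", "formation", "formation", "conversion",
                  "formation", "formation", "conversion", "conversion"),
    direction = c("activate", "activate", "activate", "activate",
                  "inhibit", "inhibit", "inhibit", "inhibit"),
    strength  = NA_real_
  )
}

.targets <- c("formation", "conversion", "degradation")
.target_abbr <- c(formation = "form", conversion = "conv", degradation = "deg")
.dir_sign <- c(activate = "+", inhibit = "-")

# single-reaction mode codes in canonical order
.single_modes <- c("none", "form+", "form-", "conv+", "conv-", "deg+", "deg-")

mode_to_rows <- function(drug, mode) {
  if (identical(mode, "none")) {
    return(data.frame(agent = character(), target = character(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(mode, "|", fixed = TRUE)[[1]]
  tgt <- names(.target_abbr)[match(substr(parts, 1, nchar(parts) - 1),
                                   .target_abbr)]
  dir <- ifelse(substr(parts, nchar(parts), nchar(parts)) == "+",
                "activate", "inhibit")
  if (any(is.na(tgt))) stop("unknown mode code: ", mode, call. = FALSE)
  data.frame(agent = drug, target = tgt, direction = dir,
             stringsAsFactors = FALSE)
}

#' Construct a mode-of-action hypothesis
#'
#' A hypothesis assigns each drug with unknown autophagic activity one mode:
#' `"none"` or a reaction/direction code such as `"deg-"` (inhibits
#' degradation) or `"form+"` (activates formation). Multi-reaction modes are
#' written with `|`, e.g. `"form+|deg-"`.
#'
#' @param modes Named character vector, `drug = mode`.
#' @return An object of class `mode_hypothesis` with a canonical,
#'   order-independent `id` such as `"CIS:deg-|EPI:none|PAC:conv-"`.
#' @examples
#' mode_hypothesis(c(CIS = "deg-", EPI = "none", PAC = "conv-"))
#' @export
mode_hypothesis <- function(modes) {
  if (is.null(names(modes)) || any(names(modes) == ""))
    stop("modes must be named by drug", call. = FALSE)
  if (anyDuplicated(names(modes)))
    stop("duplicate drug names in hypothesis", call. = FALSE)
  ord <- order(names(modes))
  modes <- vapply(modes[ord], canonical_mode, character(1))
  rows <- do.call(rbind, lapply(names(modes),
                                function(d) mode_to_rows(d, modes[[d]])))
  if (is.null(rows))
    rows <- data.frame(agent = character(), target = character(),
                       direction = character(), stringsAsFactors = FALSE)
  structure(list(modes = modes, assignments = rows,
                 id = paste(paste0(names(modes), ":", modes), collapse = "|")),
            class = "mode_hypothesis")
}

canonical_mode <- function(mode) {
  if (identical(mode, "none")) return("none")
  parts <- unique(strsplit(mode, "|", fixed = TRUE)[[1]])
  abbr <- substr(parts, 1, nchar(parts) - 1)
  if (any(!abbr %in% .target_abbr) ||
      any(!substr(parts, nchar(parts), nchar(parts)) %in% c("+", "-")))
    stop("unknown mode code: ", mode, call. = FALSE)
  if (anyDuplicated(abbr))
    stop("a drug may carry at most one direction per reaction: ", mode,
         call. = FALSE)
  parts[order(match(abbr, .target_abbr))] |> paste(collapse = "|")
}

#' @export
print.mode_hypothesis <- function(x, ...) {
  cat("<mode_hypothesis>", x$id, "\n")
  invisible(x)
}

#' Enumerate the family of mode-of-action hypotheses
#'
#' Single-mode default: each drug takes one of 7 options (none, or one of 3
#' reactions x 2 directions), giving `7^n` joint hypotheses for `n` drugs.
#' With `allow_multi_reaction` each drug takes one of `3^3 = 27` per-reaction
#' assignments from none/activate/inhibit.
#'
#' @param drugs Character vector of drug names (unique).
#' @param allow_multi_reaction Allow a drug to act on several reactions.
#' @return List of [mode_hypothesis()] objects in deterministic canonical
#'   order.
#' @examples
#' length(enumerate_hypotheses("EPI"))            # 7
#' length(enumerate_hypotheses(c("EPI", "CIS", "PAC")))  # 343
#' @export
enumerate_hypotheses <- function(drugs, allow_multi_reaction = FALSE) {
  if (length(drugs) == 0) stop("drugs must be non-empty", call. = FALSE)
  if (anyDuplicated(drugs)) stop("duplicate drug names", call. = FALSE)
  if (allow_multi_reaction) {
    per_reaction <- expand.grid(form = c("", "+", "-"), conv = c("", "+", "-"),
                                deg = c("", "+", "-"),
                                stringsAsFactors = FALSE)
    opts <- apply(per_reaction, 1, function(r) {
      parts <- paste0(c("form", "conv", "deg"), r)[r != ""]
      if (length(parts) == 0) "none" else paste(parts, collapse = "|")
    })
  } else {
    opts <- .single_modes
  }
  grids <- rep(list(opts), length(drugs))
  names(grids) <- drugs
  combos <- expand.grid(grids, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    mode_hypothesis(vapply(combos[i, , drop = FALSE], identity, character(1)))
  })
}

#' Assemble a fittable model from a hypothesis and an agent library
#'
#' Combines the fixed library assignments (free strengths) with the
#' hypothesis' drug assignments (one free strength per non-none mode) into a
#' model skeleton: a modifier table plus the named free-parameter vector
#' (3 basal rates + all strengths) with default bounds.
#'
#' @param hypothesis A [mode_hypothesis()].
#' @param library A [modifier_table()] of known-agent assignments, e.g.
#'   [agent_library()].
#' @param bounds Length-2 numeric, default `c(1e-3, 1e3)`, applied to every
#'   free parameter.
#' @param fit_scales Also fit observation scale factors `scale_AP` and
#'   `scale_AL` mapping species to measured units (default `FALSE`: data are
#'   taken as pre-normalised, since free scales are confounded with
#'   `k_form` unless some parameters are fixed).
#' @return An object of class `flux_model`: list with `modifiers`,
#'   `par_names`, `lower`, `upper`, `hypothesis_id`.
#' @examples
#' m <- build_model(mode_hypothesis(c(EPI = "deg+")), agent_library())
#' m$par_names  # 3 rates + 8 library strengths + 1 drug strength
#' @export
build_model <- function(hypothesis, library = agent_library(),
                        bounds = c(1e-3, 1e3), fit_scales = FALSE) {
  stopifnot(inherits(hypothesis, "mode_hypothesis"))
  validate_modifiers(library)
  drugs <- names(hypothesis$modes)
  if (any(drugs %in% library$agent))
    stop("drug name collides with a library agent: ",
         paste(intersect(drugs, library$agent), collapse = ", "),
         call. = FALSE)
  mods <- rbind(library[, c("agent", "target", "direction")],
                hypothesis$assignments)
  mods$param <- if (nrow(mods) > 0) {
    paste0("s_", mods$agent, "_", .target_abbr[mods$target])
  } else {
    character(0)
  }
  par_names <- c("k_form", "k_conv", "k_deg", mods$param,
                 if (fit_scales) c("scale_AP", "scale_AL"))
  structure(list(modifiers = mods, par_names = par_names,
                 lower = stats::setNames(rep(bounds[1], length(par_names)),
                                         par_names),
                 upper = stats::setNames(rep(bounds[2], length(par_names)),
                                         par_names),
                 hypothesis_id = hypothesis$id,
                 hypothesis = hypothesis),
            class = "flux_model")
}

#' @export
print.flux_model <- function(x, ...) {
  cat("<flux_model>", x$hypothesis_id, "\n",
      length(x$par_names), "free parameters\n")
  invisible(x)
}

# Concrete modifier table for a model at a given parameter vector.
model_modifiers <- function(model, par) {
  m <- model$modifiers
  m$strength <- unname(par[m$param])
  m[, c("agent", "target", "direction", "strength")]
}

# Basal rates for a model at a parameter vector.
model_params <- function(par) {
  flux_params(par[["k_form"]], par[["k_conv"]], par[["k_deg"]])
}
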