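#' The speract-activated signaling pathway (SASP) network
#'
#' Loads the bundled 21-node logical model of the Ca2+-regulating cascade
#' that speract triggers in the sea urchin sperm flagellum. Seventeen nodes
#' are binary; four are ternary: the membrane potential `V` (hyperpolarized
#' 0, resting 1, depolarized 2), the low- and high-voltage-activated Ca2+
#' channels `LVA` and `HVA` (inactive 0, closed 1, open 2) and the
#' intracellular calcium level `Ca` (basal 0, tonic 1, supratonic 2).
#'
#' The bundled truth tables are a *synthetic reconstruction*: the original
#' published tables were not available as machine-readable files, so the
#' regulatory functions were rebuilt from the documented wiring diagram and
#' the electrophysiological narrative of the pathway (see the package
#' vignette for the rule-by-rule rationale, and [sasp_reconstruction()] for
#' the programmatic definition the fixture files are generated from).
#' Structural facts of the published model are preserved exactly — 21
#' nodes, the four ternary nodes above, and a 432-row calcium table whose
#' regulators include the three activating channels (LVA, HVA, cAMPCC), the
#' two extrusion systems (CaP, NCE) and calcium's own self-inactivation —
#' but the dynamical fine print is this package's own reconstruction, not a
#' transcription.
#'
#' @return a validated [logical_network] with 21 nodes.
#' @seealso [speract_policy()], [scenario_suite()]
#' @export
sasp_network <- function() {
  dir <- system.file("extdata", "sasp_synthetic", package = "saspnet")
  if (!nzchar(dir)) stop("bundled SASP fixture not found", call. = FALSE)
  load_network(dir, metadata = "SASP 21-node network (synthetic reconstruction)")
}

#' Speract-activated initial-condition policy
#'
#' The initial-condition space used for all basin and ensemble statistics of
#' the SASP model: the speract ligand node is held at 1 (speract present)
#' and excluded from the free dimensions; every other node starts uniformly
#' at random over its value range.
#'
#' @return a named integer vector suitable for the `ic_policy` argument of
#'   [basin_statistics()] and [ensemble_average()].
#' @export
speract_policy <- function() c(Speract = 1L)

#' Programmatic definition of the reconstructed SASP network
#'
#' Builds the synthetic SASP reconstruction from its rule set (below) rather
#' than from the bundled text files; the fixture under
#' `inst/extdata/sasp_synthetic/` is generated from this function, and a
#' package test asserts the two stay identical.
#'
#' The rules, node by node (regulator order as listed):
#' \describe{
#'   \item{Speract}{self-copy (an input; clamped to 1 under the
#'     speract-activated policy).}
#'   \item{SR, GC}{receptor occupancy copies Speract; guanylate cyclase
#'     activity copies SR.}
#'   \item{cGMP}{balance of GC (synthesis) against PDE (hydrolysis); on a
#'     tie, the current cGMP level persists.}
#'   \item{PDE}{activated by its substrate cGMP (delayed negative
#'     feedback).}
#'   \item{KCNG}{the cGMP-gated K+ channel opens when cGMP is high, it was
#'     closed, and the membrane is not already hyperpolarized (no K+
#'     driving force at V = 0); it inactivates after one open step
#'     (transient hyperpolarizing current).}
#'   \item{NHE, HCN}{both recruited by hyperpolarization: active/open
#'     exactly when V = 0.}
#'   \item{cAMPCC}{cAMP-gated Ca2+ channel; the pH/cAMP limb downstream of
#'     NHE is folded into a single copy link from NHE.}
#'   \item{LVA}{voltage-gated, low threshold: recovers to closed at V = 0;
#'     from closed it opens at V >= 1; after one open step it inactivates;
#'     inactivated stays inactivated until hyperpolarization.}
#'   \item{HVA}{voltage-gated, high threshold: recovers at V = 0; opens
#'     from closed only at V = 2; deactivates to closed at V = 1;
#'     inactivates after one open step at V = 2.}
#'   \item{CaP}{the Ca2+ pump engages at tonic or higher calcium
#'     (Ca >= 1).}
#'   \item{NCE}{forward-mode Na+/Ca2+ exchange requires calcium to extrude
#'     (Ca >= 1) and a non-depolarized membrane (V <= 1).}
#'   \item{CaCC}{Ca2+-gated Cl- channel, opens at supratonic calcium
#'     (Ca = 2).}
#'   \item{CaKC}{Ca2+-gated K+ channel, opens at tonic calcium (Ca >= 1);
#'     the lower threshold than CaCC encodes its higher calcium
#'     sensitivity.}
#'   \item{Ca}{moves one level toward the sign of the drive balance:
#'     activators LVA = 2, HVA = 2, cAMPCC, HCN (weak Ca2+-permeant
#'     inward current) against inhibitors CaP, NCE and self-inactivation
#'     (Ca >= 1); 432-row table.}
#'   \item{dCa, dCl, dNa, dK}{permeability summaries: dCa is 1 when any
#'     Ca2+ conductance is open (LVA = 2, HVA = 2 or cAMPCC), dCl copies
#'     CaCC, dNa copies HCN, dK is the OR of KCNG and CaKC.}
#'   \item{V}{integrates the permeability balance: V moves one level in the
#'     direction of the sign of (dCa + dNa) - (dCl + dK), staying put on a
#'     balanced tie (the membrane potential is a graded state variable, so
#'     it cannot jump from hyperpolarized to depolarized in one step).}
#' }
#'
#' @return a validated [logical_network], identical to [sasp_network()].
#' @export
sasp_reconstruction <- function() {
  spec <- list(
    Speract = list(arity = 2L, role = "ligand", regs = "Speract",
                   f = function(g) g[, "Speract"]),
    SR      = list(arity = 2L, role = "receptor", regs = "Speract",
                   f = function(g) g[, "Speract"]),
    GC      = list(arity = 2L, role = "enzyme", regs = "SR",
                   f = function(g) g[, "SR"]),
    PDE     = list(arity = 2L, role = "enzyme", regs = "cGMP",
                   f = function(g) g[, "cGMP"]),
    cGMP    = list(arity = 2L, role = "concentration", regs = c("GC", "PDE", "cGMP"),
                   f = function(g) {
                     s <- g[, "GC"] - g[, "PDE"]
                     ifelse(s > 0, 1L, ifelse(s < 0, 0L, g[, "cGMP"]))
                   }),
    KCNG    = list(arity = 2L, role = "channel", regs = c("cGMP", "KCNG", "V"),
                   f = function(g) as.integer(g[, "cGMP"] == 1 & g[, "KCNG"] == 0 &
                                                g[, "V"] >= 1)),
    NHE     = list(arity = 2L, role = "exchanger", regs = "V",
                   f = function(g) as.integer(g[, "V"] == 0)),
    cAMPCC  = list(arity = 2L, role = "channel", regs = "NHE",
                   f = function(g) g[, "NHE"]),
    HCN     = list(arity = 2L, role = "channel", regs = "V",
                   f = function(g) as.integer(g[, "V"] == 0)),
    LVA     = list(arity = 3L, role = "channel", regs = c("V", "LVA"),
                   f = function(g) {
                     v <- g[, "V"]; x <- g[, "LVA"]
                     ifelse(v == 0, 1L, ifelse(x == 1L, 2L, 0L))
                   }),
    HVA     = list(arity = 3L, role = "channel", regs = c("V", "HVA"),
                   f = function(g) {
                     v <- g[, "V"]; x <- g[, "HVA"]
                     ifelse(v == 0, 1L,
                       ifelse(v == 1, ifelse(x == 2L, 1L, x),
                         ifelse(x == 1L, 2L, 0L)))
                   }),
    CaP     = list(arity = 2L, role = "pump", regs = "Ca",
                   f = function(g) as.integer(g[, "Ca"] >= 1)),
    NCE     = list(arity = 2L, role = "exchanger", regs = c("V", "Ca"),
                   f = function(g) as.integer(g[, "Ca"] >= 1 & g[, "V"] <= 1)),
    CaCC    = list(arity = 2L, role = "channel", regs = "Ca",
                   f = function(g) as.integer(g[, "Ca"] == 2)),
    CaKC    = list(arity = 2L, role = "channel", regs = "Ca",
                   f = function(g) as.integer(g[, "Ca"] >= 1)),
    Ca      = list(arity = 3L, role = "concentration",
                   regs = c("LVA", "HVA", "cAMPCC", "HCN", "CaP", "NCE", "Ca"),
                   f = function(g) {
                     act <- (g[, "LVA"] == 2) + (g[, "HVA"] == 2) +
                       g[, "cAMPCC"] + g[, "HCN"]
                     inh <- g[, "CaP"] + g[, "NCE"] + (g[, "Ca"] >= 1)
                     pmin(pmax(g[, "Ca"] + sign(act - inh), 0), 2)
                   }),
    dCa     = list(arity = 2L, role = "permeability",
                   regs = c("LVA", "HVA", "cAMPCC"),
                   f = function(g) as.integer(g[, "LVA"] == 2 | g[, "HVA"] == 2 |
                                                g[, "cAMPCC"] == 1)),
    dCl     = list(arity = 2L, role = "permeability", regs = "CaCC",
                   f = function(g) g[, "CaCC"]),
    dNa     = list(arity = 2L, role = "permeability", regs = "HCN",
                   f = function(g) g[, "HCN"]),
    dK      = list(arity = 2L, role = "permeability", regs = c("KCNG", "CaKC"),
                   f = function(g) as.integer(g[, "KCNG"] == 1 | g[, "CaKC"] == 1)),
    V       = list(arity = 3L, role = "voltage",
                   regs = c("dCa", "dCl", "dNa", "dK", "V"),
                   f = function(g) {
                     s <- (g[, "dCa"] + g[, "dNa"]) - (g[, "dCl"] + g[, "dK"])
                     pmin(pmax(g[, "V"] + sign(s), 0), 2)
                   })
  )
  nodes <- tibble::tibble(
    name = names(spec),
    arity = vapply(spec, `[[`, integer(1), "arity"),
    regulators = lapply(spec, `[[`, "regs"),
    role = vapply(spec, `[[`, character(1), "role")
  )
  net0 <- structure(list(nodes = nodes, tables = NULL, metadata = ""),
                    class = "logical_network")
  tables <- lapply(seq_len(nrow(nodes)), function(i) {
    g <- regulator_grid(net0, i)
    as.integer(spec[[nodes$name[i]]]$f(g))
  })
  names(tables) <- nodes$name
  logical_network(nodes, tables,
                  metadata = "SASP 21-node network (synthetic reconstruction)")
}
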