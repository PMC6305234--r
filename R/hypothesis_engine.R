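# The sixteen "most relevant DE" selection hypotheses: which of a protein's
# DE motifs is taken as the putative secretion signal. Each case is one
# combination of (preferred order class) x (border regrouping) x
# (charge extreme) x (hydrophobicity extreme).

#' Enumerate the 16 DE-selection hypothesis cases
#'
#' The cases are the Cartesian product of four binary choices, in canonical
#' nesting order: `order_pref` (O then D) outermost, then `border_regroup`
#' (B regrouped to O, then to D), then `charge_extreme` (min, max), then
#' `hydro_extreme` (min, max). Case ids 1-16 are stable across runs; a
#' different numbering (e.g. from an external table) can be applied by
#' reordering rows on these four columns.
#'
#' @return data frame with columns `case_id`, `order_pref`,
#'   `border_regroup`, `charge_extreme`, `hydro_extreme`.
#' @export
enumerate_cases <- function() {
  grid <- expand.grid(hydro_extreme = c("min", "max"),
                      charge_extreme = c("min", "max"),
                      border_regroup = c("O", "D"),
                      order_pref = c("O", "D"),
                      stringsAsFactors = FALSE)
  data.frame(case_id = seq_len(16L),
             order_pref = grid$order_pref,
             border_regroup = grid$border_regroup,
             charge_extreme = grid$charge_extreme,
             hydro_extreme = grid$hydro_extreme,
             stringsAsFactors = FALSE)
}

get_case <- function(case) {
  if (is.numeric(case)) {
    cases <- enumerate_cases()
    stopifnot(case %in% cases$case_id)
    case <- cases[cases$case_id == case, , drop = FALSE]
  }
  stopifnot(is.data.frame(case), nrow(case) == 1L,
            all(c("order_pref", "border_regroup",
                  "charge_extreme", "hydro_extreme") %in% names(case)))
  case
}

# Vectorised representative-DE selection over a whole context table.
# Returns one row per protein (in first-appearance order) with the selected
# motif's features, the order indicator after regrouping, and a fallback
# flag for proteins with no motif in the preferred class.
select_by_case <- function(contexts, case) {
  case <- get_case(case)
  if (nrow(contexts) == 0) stop("empty context table")
  if (anyNA(contexts$order_class))
    stop("order class undefined for some motifs; drop proteins without ",
         "structure strings before hypothesis selection")
  pid <- factor(contexts$protein_id, levels = unique(contexts$protein_id))
  oc <- contexts$order_class
  oc[oc == "B"] <- case$border_regroup
  pref <- oc == case$order_pref
  has_pref <- as.logical(ave(pref, pid, FUN = any))
  eligible <- pref | !has_pref
  ckey <- if (case$charge_extreme == "min") contexts$C else -contexts$C
  hkey <- if (case$hydro_extreme == "min") contexts$H else -contexts$H
  ord <- order(as.integer(pid), !eligible, ckey, hkey, contexts$start,
               method = "radix")
  first <- ord[!duplicated(as.integer(pid)[ord])]
  first <- first[order(as.integer(pid)[first])]   # back to dataset order
  sel <- contexts[first, , drop = FALSE]
  sel$order_indicator <- as.integer(oc[first] == "O")
  sel$fallback <- !has_pref[first]
  rownames(sel) <- NULL
  sel
}

#' Select the most relevant DE motif of one protein under a hypothesis case
#'
#' Applies the case's border regrouping, restricts to motifs of the
#' preferred order class (falling back to all motifs, flagged, when none
#' exist), then picks the extreme by the charge criterion, breaking ties by
#' the hydrophobicity criterion and remaining ties by the smallest start
#' position.
#'
#' @param contexts context rows of a single protein (see
#'   [annotate_dataset()]); order classes must be defined.
#' @param case a `case_id` (1-16) or a single row of [enumerate_cases()].
#' @return the selected context row with extra columns `order_indicator`
#'   (1 if the selected DE is ordered after regrouping) and `fallback`.
#' @export
select_representative_de <- function(contexts, case) {
  if (nrow(contexts) == 0) stop("empty context list")
  if (length(unique(contexts$protein_id)) > 1L)
    stop("contexts from more than one protein; use select_by_case()")
  select_by_case(contexts, case)
}

#' Build the per-case design matrix
#'
#' One row per protein: the (H, C, order) features of the representative DE
#' selected under `case`, plus the binary secretion label (secretory = 1).
#' Proteins labelled `unknown` are excluded.
#'
#' @param contexts annotated context table from [annotate_dataset()]
#'   (must carry the `label` column).
#' @param case a `case_id` or case row.
#' @return data frame with columns `protein_id`, `label`, `H`, `C`,
#'   `order_indicator`, `selected_start`, `fallback`.
#' @export
build_design_matrix <- function(contexts, case) {
  contexts <- contexts[contexts$label %in% c("secretory", "non_secretory"), ,
                       drop = FALSE]
  if (nrow(contexts) == 0) stop("no labelled proteins in context table")
  sel <- select_by_case(contexts, case)
  data.frame(protein_id = sel$protein_id,
             label = as.integer(sel$label == "secretory"),
             H = sel$H, C = sel$C,
             order_indicator = sel$order_indicator,
             selected_start = sel$start,
             fallback = sel$fallback,
             stringsAsFactors = FALSE)
}

#' Per-protein extreme features over all DE motifs
#'
#' The minimum and maximum flanking charge and hydrophobicity over every DE
#' occurrence of one protein.
#'
#' @param contexts context rows of a single protein.
#' @return one-row data frame with `protein_id`, `min_charge`,
#'   `max_charge`, `min_hydro`, `max_hydro`.
#' @export
extreme_features <- function(contexts) {
  if (nrow(contexts) == 0) stop("empty context list")
  data.frame(protein_id = contexts$protein_id[1],
             min_charge = min(contexts$C), max_charge = max(contexts$C),
             min_hydro = min(contexts$H), max_hydro = max(contexts$H),
             stringsAsFactors = FALSE)
}

# Extreme features for every protein in a context table, with labels.
extreme_features_all <- function(contexts) {
  pid <- factor(contexts$protein_id, levels = unique(contexts$protein_id))
  out <- do.call(rbind, lapply(split(contexts, pid), extreme_features))
  meta <- contexts[!duplicated(contexts$protein_id),
                   c("protein_id", "label", "group")]
  out <- merge(out, meta, by = "protein_id", sort = FALSE)
  rownames(out) <- NULL
  out
}
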