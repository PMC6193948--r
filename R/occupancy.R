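# Per-site ligand occupancy analysis for a hexameric (trimer-of-dimers)
# enzyme: site classification by own + partner active-site conformation,
# class mean occupancies, and the order in which site classes fill along a
# ligand:protein titration series.

SITE_CLASSES <- c("closed", "open_in_closed_open_dimer",
                  "open_in_open_open_dimer")

#' Per-chain active-site occupancy table for one complex
#'
#' One hexamer (or symmetry-expanded half-hexamer) at one ligand:protein
#' molar ratio: for each chain, its active-site conformation, its dimer
#' partner, and the refined ligand occupancy factor. Sites modelled
#' without ligand ("no FA") are stored as `NA`, not 0, to distinguish
#' unmodelled from weakly occupied.
#'
#' @param structure_id structure label, e.g. `"WT-6(P/S)-2FA"`.
#' @param molar_ratio ligand molecules per hexamer in the crystallisation
#'   drop (dimensionless, >= 0).
#' @param chain chain identifiers (symmetry mates may carry primes, e.g.
#'   `"B'"`).
#' @param conformation `"open"` or `"closed"` per chain.
#' @param partner the dimer partner of each chain; the map must be
#'   symmetric and each chain must belong to exactly one dimer.
#' @param occupancy ligand occupancy factor in `[0, 1]`, or `NA` for no
#'   modelled ligand.
#' @return A `data.frame` of class `"occupancy_table"` with attribute
#'   `structure_id` and `molar_ratio`.
#' @export
occupancy_table <- function(structure_id, molar_ratio, chain, conformation,
                            partner, occupancy) {
  n <- length(chain)
  stopifnot(length(conformation) == n, length(partner) == n,
            length(occupancy) == n)
  if (anyDuplicated(chain)) stop("duplicated chain ids", call. = FALSE)
  if (!all(conformation %in% c("open", "closed")))
    stop("conformation must be 'open' or 'closed'", call. = FALSE)
  if (any(!is.na(occupancy) & (occupancy < 0 | occupancy > 1)))
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  if (!all(partner %in% chain))
    stop("every partner must be a chain of the table", call. = FALSE)
  # dimer map symmetry: partner(partner(x)) == x and no self-pairing
  idx <- match(partner, chain)
  if (any(partner == chain) || !all(partner[idx] == chain))
    stop("dimer map must pair each chain with exactly one other chain",
         call. = FALSE)
  out <- data.frame(chain = chain, conformation = conformation,
                    partner = partner, occupancy = occupancy)
  structure(out, structure_id = structure_id, molar_ratio = molar_ratio,
            class = c("occupancy_table", "data.frame"))
}

#' Classify each active site by its own and its partner's conformation
#'
#' Closed sites form one class; open sites split by the conformation of
#' their dimer partner into open-in-closed-open-dimer and
#' open-in-open-open-dimer. In the hexamer these are the three
#' symmetry-distinct site environments.
#'
#' @param table an [occupancy_table()].
#' @return Named character vector, chain id -> site class (one of
#'   `"closed"`, `"open_in_closed_open_dimer"`,
#'   `"open_in_open_open_dimer"`).
#' @export
classify_sites <- function(table) {
  stopifnot(inherits(table, "occupancy_table"))
  partner_conf <- table$conformation[match(table$partner, table$chain)]
  cls <- ifelse(table$conformation == "closed", "closed",
         ifelse(partner_conf == "closed", "open_in_closed_open_dimer",
                "open_in_open_open_dimer"))
  stats::setNames(cls, table$chain)
}

#' Mean ligand occupancy of one site class
#'
#' Arithmetic mean of the occupancy factors over the member sites of the
#' class; sites with no modelled ligand count as 0.
#'
#' @param table an [occupancy_table()].
#' @param site_class one of the three site classes (see
#'   [classify_sites()]).
#' @return Mean occupancy in `[0, 1]`, or `NA` if the class has no member
#'   chains in this hexamer.
#' @export
class_mean_occupancy <- function(table, site_class) {
  site_class <- match.arg(site_class, SITE_CLASSES)
  cls <- classify_sites(table)
  member <- names(cls)[cls == site_class]
  if (!length(member)) return(NA_real_)
  occ <- table$occupancy[match(member, table$chain)]
  occ[is.na(occ)] <- 0
  mean(occ)
}

#' Site-class filling order along a titration series
#'
#' For each site class, finds the smallest molar ratio in the series at
#' which its mean occupancy reaches `occ_threshold`, and orders the
#' classes by that ratio (classes that never reach the threshold come
#' last, with `first_ratio = NA`). This is the quantity that distinguishes
#' closed-sites-first binding (wild-type-like) from open-sites-first
#' binding.
#'
#' @param series a list of [occupancy_table()] objects with increasing
#'   `molar_ratio` attributes.
#' @param occ_threshold occupancy deemed "present", in (0, 1); default 0.4,
#'   the smallest occupancy factor reported in the packaged series.
#' @return A `data.frame` sorted by filling order with columns
#'   `site_class`, `first_ratio` (`NA` = never) and `max_occupancy`.
#' @export
#' @examples
#' fx <- pnp_fa_occupancy()
#' wt <- fx[grep("^WT", names(fx))]
#' filling_order(wt)
filling_order <- function(series, occ_threshold = 0.4) {
  if (!length(series)) stop("empty occupancy series", call. = FALSE)
  stopifnot(all(vapply(series, inherits, logical(1), "occupancy_table")))
  if (occ_threshold <= 0 || occ_threshold >= 1)
    stop("'occ_threshold' must be in (0, 1)", call. = FALSE)
  ratios <- vapply(series, attr, numeric(1), "molar_ratio")
  series <- series[order(ratios)]
  ratios <- sort(ratios)
  rows <- lapply(SITE_CLASSES, function(cl) {
    occ <- vapply(series, class_mean_occupancy, numeric(1), site_class = cl)
    if (all(is.na(occ))) return(NULL)  # class absent from every hexamer
    hit <- which(!is.na(occ) & occ >= occ_threshold)
    data.frame(site_class = cl,
               first_ratio = if (length(hit)) ratios[min(hit)] else NA_real_,
               max_occupancy = max(occ, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$first_ratio), out$first_ratio), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Packaged FA occupancy series for wild-type and double-mutant PNP
#'
#' Transcription of the published per-chain formycin A (FA) occupancy
#' factors for five ternary-complex crystal structures of hexameric
#' E. coli purine nucleoside phosphorylase obtained at increasing FA:PNP
#' molar ratios (two wild-type, three Asp204Ala/Arg217Ala double-mutant
#' structures). Hexagonal structures, in which half the hexamer is
#' generated by a crystallographic two-fold, are stored symmetry-expanded
#' (primed chains) so both space groups share one data model. "No FA"
#' sites are `NA`.
#'
#' @return Named list of [occupancy_table()] objects, one per structure,
#'   ordered by molar ratio within enzyme form.
#' @export
pnp_fa_occupancy <- function() {
  path <- system.file("extdata", "pnp_fa_occupancy.csv",
                      package = "allokin", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$structure_id), function(s) {
    occupancy_table(structure_id = s$structure_id[1],
                    molar_ratio = s$molar_ratio[1],
                    chain = s$chain, conformation = s$conformation,
                    partner = s$partner, occupancy = s$occupancy)
  })
  ratios <- vapply(out, attr, numeric(1), "molar_ratio")
  forms <- substr(names(out), 1, 2)
  out[order(forms, ratios)]
}

#' Build synthetic hexamer occupancy tables from per-class titrations
#'
#' Maps [simulate_titration()] output onto the canonical hexamer topology
#' (chains A-F, closed A and F, dimers A-D, F-C, B-E), assigning each site
#' class the `site_occupancy` of its own titration. With one titration per
#' class (different association constants), this produces a ground-truth
#' filling order against which [filling_order()] inference can be checked.
#'
#' @param closed,open_co,open_oo data.frames from [simulate_titration()]
#'   over a common `ratio` column, for the closed sites, the open sites of
#'   closed-open dimers, and the open sites of the open-open dimer. If
#'   only `closed` is given, all classes share it.
#' @return A list of [occupancy_table()] objects, one per titration ratio.
#' @export
titration_to_occupancy <- function(closed, open_co = closed,
                                   open_oo = closed) {
  if (!isTRUE(all.equal(closed$ratio, open_co$ratio)) ||
      !isTRUE(all.equal(closed$ratio, open_oo$ratio)))
    stop("the three titrations must share the same ratios", call. = FALSE)
  chains <- c("A", "B", "C", "D", "E", "F")
  conformation <- c("closed", "open", "open", "open", "open", "closed")
  partner <- c("D", "E", "F", "A", "B", "C")
  # class per chain under this topology: A,F closed; D,C open-in-CO; B,E open-open
  lapply(seq_len(nrow(closed)), function(i) {
    occ <- c(closed$site_occupancy[i], open_oo$site_occupancy[i],
             open_co$site_occupancy[i], open_co$site_occupancy[i],
             open_oo$site_occupancy[i], closed$site_occupancy[i])
    occupancy_table(structure_id = sprintf("synthetic-ratio-%g",
                                           closed$ratio[i]),
                    molar_ratio = closed$ratio[i],
                    chain = chains, conformation = conformation,
                    partner = partner, occupancy = pmin(occ, 1))
  })
}
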