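PRIMATE_PANEL <- c(
  "Homo_sapiens", "Gorilla_gorilla", "Pan_paniscus", "Pan_troglodytes",
  "Pongo_pygmaeus", "Pongo_abelii", "Hylobates_lar", "Macaca_mulatta",
  "Macaca_sylvanus", "Papio_hamadryas", "Cebus_albifrons",
  "Tarsius_bancanus", "Nycticebus_coucang", "Lemur_catta")

.other_bases <- function(b) setdiff(c("A", "C", "G", "T"), b)

#' Specification for a synthetic conservation alignment
#'
#' @param targets named integer vector: rCRS position -> number of panel
#'   species (human included) that must carry the human base there
#' @param background divergence probability per non-human row at
#'   unspecified positions (default 0.1)
#' @param seed RNG seed
#' @param n_species panel size (default 14)
#' @return a `ConservationSpec` list
#' @export
conservation_spec <- function(targets, background = 0.1, seed = 1,
                              n_species = 14) {
  targets <- stats::setNames(as.integer(targets), names(targets))
  if (any(targets < 1 | targets > n_species))
    stop("impossible conservation target (must be 1..", n_species, ")",
         call. = FALSE)
  structure(list(targets = targets, background = background,
                 seed = as.integer(seed), n_species = as.integer(n_species)),
            class = "ConservationSpec")
}

#' Generate a primate alignment with controlled per-position conservation
#'
#' Emulates the 14-primate panel: a gapless alignment over the reference
#' region whose human row is the reference itself. At every specified
#' position exactly `target` rows (human included) carry the reference
#' base; substituted rows receive a uniformly chosen different base.
#' Unspecified positions diverge at the background rate. Pure function of
#' (spec, seed).
#'
#' @param ref an `MtReference`
#' @param spec a `ConservationSpec`
#' @return a `PrimateAlignment`
#' @export
generate_primate_alignment <- function(ref, spec) {
  pos <- as.integer(names(spec$targets))
  if (any(pos < ref$region_start | pos > ref$region_end))
    stop("conservation target outside region", call. = FALSE)
  set.seed(spec$seed)
  refchars <- strsplit(region_sequence(ref), "")[[1]]
  n <- length(refchars)
  k <- spec$n_species
  mat <- matrix(rep(refchars, each = k), nrow = k)
  for (r in 2:k) {
    hit <- which(stats::runif(n) < spec$background)
    for (j in hit) mat[r, j] <- sample(.other_bases(refchars[j]), 1)
  }
  for (t in seq_along(pos)) {
    j <- pos[t] - ref$region_start + 1L
    keep <- sample(2:k, spec$targets[t] - 1L)   # human row always matches
    mat[, j] <- refchars[j]
    for (r in setdiff(2:k, keep))
      mat[r, j] <- sample(.other_bases(refchars[j]), 1)
  }
  primate_alignment(PRIMATE_PANEL[seq_len(k)],
                    apply(mat, 1, paste, collapse = ""),
                    human_id = PRIMATE_PANEL[1],
                    region_start = ref$region_start, ref = ref)
}

#' Conservation spec matching the packaged variant catalogue
#'
#' Targets are the species counts recovered from the catalogue's CI column
#' (one target per distinct position).
#'
#' @param variants variant table as from [load_variant_table()]
#' @param seed RNG seed
#' @param background background divergence rate
#' @return a `ConservationSpec`
#' @export
fixture_conservation_spec <- function(variants = load_variant_table(),
                                      seed = 1, background = 0.1) {
  keep <- !duplicated(variants$position)
  conservation_spec(
    stats::setNames(ci_to_matches(variants$ci_percent[keep]),
                    variants$position[keep]),
    background = background, seed = seed)
}

#' Plant variants into the reference region
#'
#' Builds a subject sequence differing from the reference region exactly at
#' the planted sites. Variants may be given as names (legacy aliases are
#' resolved to canonical coordinates) or as a parsed data.frame.
#'
#' @param ref an `MtReference`
#' @param variants character vector of names or data.frame (position, ref,
#'   alt, kind)
#' @param aliases legacy alias map used for name resolution
#' @return nucleotide string
#' @export
plant_variants <- function(ref, variants,
                           aliases = load_insertion_aliases()) {
  if (is.character(variants)) {
    if (length(variants) == 0) return(region_sequence(ref))
    variants <- parse_variant_name(variants, aliases)
  }
  chars <- strsplit(region_sequence(ref), "")[[1]]
  if (nrow(variants) == 0) return(paste(chars, collapse = ""))
  span <- function(v) {
    if (v$kind == "insertion") c(NA_integer_, NA_integer_)
    else c(v$position, v$position + nchar(v$ref) - 1L)
  }
  occ <- integer(); anchors <- integer()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$kind == "insertion") {
      if (v$position %in% anchors) stop("overlapping insertions", call. = FALSE)
      anchors <- c(anchors, v$position)
    } else {
      s <- span(v)
      if (any(s[1]:s[2] %in% occ))
        stop("overlapping variants at position ", s[1], call. = FALSE)
      occ <- c(occ, s[1]:s[2])
    }
  }
  ord <- order(variants$position, decreasing = TRUE)
  for (i in ord) {
    v <- variants[i, ]
    j <- v$position - ref$region_start + 1L
    if (v$kind == "substitution") {
      if (chars[j] != v$ref)
        stop("ref-base mismatch at ", v$position, ": reference has ",
             chars[j], ", variant expects ", v$ref, call. = FALSE)
      chars[j] <- v$alt
    } else if (v$kind == "deletion") {
      del <- j:(j + nchar(v$ref) - 1L)
      if (paste(chars[del], collapse = "") != v$ref)
        stop("ref-base mismatch for deletion at ", v$position, call. = FALSE)
      chars <- chars[-del]
    } else {
      chars <- append(chars, strsplit(v$alt, "")[[1]], after = j)
    }
  }
  paste(chars, collapse = "")
}

#' Cohort simulation plan
#'
#' Study conditions for a synthetic case/control cohort: sample sizes,
#' exposure counts, per-variant carrier counts (optionally split by
#' exposure), severity histograms per exposure subgroup, and the set of
#' variants whose carriers are mutually exclusive (the known and putative
#' deafness mutations form non-overlapping carrier groups).
#'
#' @param n_cases,n_controls,n_exposed subgroup sizes
#' @param n_male,n_exposed_male male counts overall and among exposed
#' @param variant_plan data.frame (name, case_carriers, control_carriers,
#'   exposed_carriers with NA = unconstrained)
#' @param severity_plan list of named histograms `exposed` and `unexposed`;
#'   each must sum to its subgroup size
#' @param exclusive variant names assigned to mutually exclusive carriers
#' @param seed RNG seed
#' @return a `CohortSpec` list
#' @export
cohort_spec <- function(n_cases, n_controls, n_exposed,
                        variant_plan, severity_plan,
                        n_male = round(n_cases / 2),
                        n_exposed_male = round(n_exposed / 2),
                        exclusive = character(), seed = 1) {
  stopifnot(n_exposed <= n_cases, n_exposed_male <= n_exposed,
            n_male <= n_cases)
  if (!"exposed_carriers" %in% names(variant_plan))
    variant_plan$exposed_carriers <- NA_integer_
  if (any(variant_plan$case_carriers > n_cases) ||
      any(variant_plan$control_carriers > n_controls))
    stop("infeasible plan: carrier count exceeds denominator", call. = FALSE)
  ec <- variant_plan$exposed_carriers
  if (any(!is.na(ec) & (ec > variant_plan$case_carriers | ec > n_exposed)))
    stop("infeasible plan: exposed carriers exceed bounds", call. = FALSE)
  if (sum(severity_plan$exposed) != n_exposed ||
      sum(severity_plan$unexposed) != n_cases - n_exposed)
    stop("severity histograms must sum to subgroup sizes", call. = FALSE)
  if (!all(c(names(severity_plan$exposed), names(severity_plan$unexposed))
           %in% SEVERITY_LEVELS))
    stop("unknown severity grade in plan", call. = FALSE)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_exposed = as.integer(n_exposed),
                 n_male = as.integer(n_male),
                 n_exposed_male = as.integer(n_exposed_male),
                 variant_plan = variant_plan,
                 severity_plan = severity_plan,
                 exclusive = exclusive, seed = as.integer(seed)),
            class = "CohortSpec")
}

#' The packaged study conditions
#'
#' The cohort spec reproducing the screened study's marginals: 440 cases
#' (227 male), 449 controls, 98 aminoglycoside-exposed cases (58 male),
#' the catalogue's per-variant case/control carrier counts, the clinical
#' table's exposure split for the known and putative mutation carriers
#' (21/2/2 exposed carriers of the three known mutations; 2 of the 5
#' putative carriers exposed), and the severity histograms 22 severe + 76
#' profound (exposed) and 26 moderate + 167 severe + 149 profound
#' (unexposed). Carriers of known/putative mutations are mutually
#' exclusive.
#'
#' @param variants variant table as from [load_variant_table()]
#' @param seed RNG seed
#' @return a `CohortSpec`
#' @export
default_cohort_spec <- function(variants = load_variant_table(), seed = 1) {
  plan <- data.frame(name = variants$name,
                     case_carriers = variants$case_count,
                     control_carriers = variants$control_count,
                     exposed_carriers = NA_integer_,
                     stringsAsFactors = FALSE)
  exposed_known <- c("1555A>G" = 21L, "1494C>T" = 2L, "1095T>C" = 2L,
                     "747A>G" = 1L, "839A>G" = 1L, "1027A>G" = 0L,
                     "1310C>T" = 0L, "1413T>C" = 0L)
  idx <- match(names(exposed_known), plan$name)
  plan$exposed_carriers[idx] <- exposed_known
  cohort_spec(n_cases = 440, n_controls = 449, n_exposed = 98,
              n_male = 227, n_exposed_male = 58,
              variant_plan = plan,
              severity_plan = list(
                exposed = c(severe = 22, profound = 76),
                unexposed = c(moderate = 26, severe = 167, profound = 149)),
              exclusive = names(exposed_known), seed = seed)
}

#' Five audiometric thresholds with a prescribed mean
#'
#' Draws thresholds at 500/1000/2000/4000/8000 Hz uniformly around the
#' target and recenters them so the PTA equals `pta_db` exactly.
#'
#' @param pta_db target pure-tone average (dB)
#' @param spread maximal per-frequency deviation before recentring
#' @return numeric vector of five non-negative thresholds
#' @export
generate_audiogram <- function(pta_db, spread = 10) {
  s <- min(spread, pta_db / 2)  # centring can at most double a deviation
  d <- stats::runif(5, -s, s)
  pta_db + d - mean(d)
}

.occupied <- function(v) if (v$kind == "insertion") integer() else
  v$position:(v$position + nchar(v$ref) - 1L)

# sample `n_exp` carriers from exposed eligibles and the rest from
# unexposed; NA n_exp means unconstrained
.pick_carriers <- function(n, n_exp, eligible, exposed_ids) {
  if (is.na(n_exp)) {
    if (length(eligible) < n) stop("infeasible plan: carrier pool exhausted",
                                   call. = FALSE)
    return(sample(eligible, n))
  }
  pool_e <- intersect(eligible, exposed_ids)
  pool_u <- setdiff(eligible, exposed_ids)
  if (length(pool_e) < n_exp || length(pool_u) < n - n_exp)
    stop("infeasible plan: exposure-stratified pool exhausted", call. = FALSE)
  c(sample(pool_e, n_exp), sample(pool_u, n - n_exp))
}

#' Generate a synthetic case/control cohort with planted variants
#'
#' Produces case and control amplicon sequences whose re-called aggregate
#' carrier counts equal the plan exactly, a subject table with exposure
#' flags, sexes, per-ear PTA and severity drawn to match the severity
#' histograms, and a manifest recording the ground truth. Byte-identical
#' across runs for a fixed (spec, seed).
#'
#' @param ref an `MtReference`
#' @param spec a `CohortSpec`
#' @param sequences generate the planted sequences (TRUE) or only the
#'   subject table and manifest
#' @param aliases legacy alias map for name resolution
#' @return list: `subjects` data.frame, `case_seqs`, `control_seqs` (named
#'   character vectors, NULL unless `sequences`), `manifest`
#' @export
generate_cohort <- function(ref, spec, sequences = TRUE,
                            aliases = load_insertion_aliases()) {
  set.seed(spec$seed)
  plan <- spec$variant_plan
  parsed <- parse_variant_name(plan$name, aliases)
  case_ids <- sprintf("CASE%04d", seq_len(spec$n_cases))
  ctrl_ids <- sprintf("CTRL%04d", seq_len(spec$n_controls))
  exposed_ids <- sample(case_ids, spec$n_exposed)

  sex <- stats::setNames(rep("F", spec$n_cases), case_ids)
  sex[sample(exposed_ids, spec$n_exposed_male)] <- "M"
  unexp <- setdiff(case_ids, exposed_ids)
  sex[sample(unexp, spec$n_male - spec$n_exposed_male)] <- "M"

  carried <- stats::setNames(vector("list", spec$n_cases), case_ids)
  occupied <- stats::setNames(vector("list", spec$n_cases), case_ids)
  excl_taken <- character()
  assign_var <- function(i, ids, n, n_exp) {
    v <- parsed[i, ]
    eligible <- ids[vapply(ids, function(s)
      !any(.occupied(v) %in% occupied[[s]]) &&
        !(v$kind == "insertion" && v$position %in% occupied[[s]]),
      logical(1))]
    if (plan$name[i] %in% spec$exclusive)
      eligible <- setdiff(eligible, excl_taken)
    picked <- .pick_carriers(n, n_exp, eligible, exposed_ids)
    for (s in picked) {
      carried[[s]] <<- c(carried[[s]], plan$name[i])
      occupied[[s]] <<- c(occupied[[s]], .occupied(v),
                          if (v$kind == "insertion") v$position)
    }
    if (plan$name[i] %in% spec$exclusive)
      excl_taken <<- c(excl_taken, picked)
    picked
  }
  # exclusive variants first so their disjoint pools are never starved
  ord <- order(!plan$name %in% spec$exclusive)
  case_truth <- list()
  for (i in ord)
    case_truth[[plan$name[i]]] <-
      assign_var(i, case_ids, plan$case_carriers[i], plan$exposed_carriers[i])

  sev <- stats::setNames(character(spec$n_cases), case_ids)
  sev[sample(exposed_ids)] <-
    rep(names(spec$severity_plan$exposed), spec$severity_plan$exposed)
  sev[sample(unexp)] <-
    rep(names(spec$severity_plan$unexposed), spec$severity_plan$unexposed)
  intervals <- list(normal = c(0, 25), mild = c(26, 40), moderate = c(41, 70),
                    severe = c(71, 90), profound = c(91, 120))
  worse <- vapply(sev, function(g) {
    iv <- intervals[[g]]
    round_half_up(mean(stats::runif(5, iv[1], iv[2])), 1)
  }, numeric(1))
  better <- vapply(worse, function(w)
    round_half_up(stats::runif(1, max(0, w - 25), w), 1), numeric(1))
  right_worse <- stats::runif(spec$n_cases) < 0.5
  subjects <- data.frame(
    subject_id = case_ids, sex = unname(sex),
    exposed = case_ids %in% exposed_ids,
    onset_age_years = sample(0:10, spec$n_cases, replace = TRUE),
    pta_right_db = ifelse(right_worse, worse, better),
    pta_left_db = ifelse(right_worse, better, worse),
    severity = unname(sev),
    variants = vapply(carried, function(v)
      paste(v, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)

  ctrl_carried <- stats::setNames(vector("list", spec$n_controls), ctrl_ids)
  ctrl_occ <- stats::setNames(vector("list", spec$n_controls), ctrl_ids)
  ctrl_truth <- list()
  for (i in seq_len(nrow(plan))) {
    n <- plan$control_carriers[i]
    if (n == 0) { ctrl_truth[[plan$name[i]]] <- character(); next }
    v <- parsed[i, ]
    eligible <- ctrl_ids[vapply(ctrl_ids, function(s)
      !any(.occupied(v) %in% ctrl_occ[[s]]) &&
        !(v$kind == "insertion" && v$position %in% ctrl_occ[[s]]),
      logical(1))]
    if (length(eligible) < n)
      stop("infeasible plan: control pool exhausted", call. = FALSE)
    picked <- sample(eligible, n)
    for (s in picked) {
      ctrl_carried[[s]] <- c(ctrl_carried[[s]], plan$name[i])
      ctrl_occ[[s]] <- c(ctrl_occ[[s]], .occupied(v),
                         if (v$kind == "insertion") v$position)
    }
    ctrl_truth[[plan$name[i]]] <- picked
  }

  case_seqs <- control_seqs <- NULL
  if (sequences) {
    case_seqs <- vapply(case_ids, function(s)
      plant_variants(ref, if (length(carried[[s]])) carried[[s]] else
        character(), aliases), character(1))
    control_seqs <- vapply(ctrl_ids, function(s)
      plant_variants(ref, if (length(ctrl_carried[[s]])) ctrl_carried[[s]]
        else character(), aliases), character(1))
  }
  realized <- plan
  realized$case_carriers <- vapply(plan$name, function(nm)
    length(case_truth[[nm]]), integer(1))
  realized$control_carriers <- vapply(plan$name, function(nm)
    length(ctrl_truth[[nm]]), integer(1))
  realized$exposed_carriers <- vapply(plan$name, function(nm)
    sum(case_truth[[nm]] %in% exposed_ids), integer(1))
  list(subjects = subjects, case_seqs = case_seqs,
       control_seqs = control_seqs,
       manifest = list(spec = spec, realized_plan = realized,
                       case_carriers = case_truth,
                       control_carriers = ctrl_truth))
}

#' Generate per-allele GJB2 sequences from a plan
#'
#' @param ref_cds GJB2 reference as from [load_gjb2_reference()]
#' @param plan named list: subject id -> list of one or two character
#'   vectors of variant names per allele (empty vector = wild type)
#' @param seed RNG seed (kept for interface symmetry; generation is
#'   deterministic given the plan)
#' @return named character vector with ids "subject|allele"
#' @export
generate_gjb2_alleles <- function(ref_cds, plan, seed = 1) {
  set.seed(seed)
  out <- character(); ids <- character()
  for (s in names(plan)) {
    alleles <- plan[[s]]
    for (a in seq_along(alleles)) {
      out <- c(out, plant_variants(ref_cds, alleles[[a]], aliases = NULL))
      ids <- c(ids, paste0(s, "|", a))
    }
  }
  stats::setNames(out, ids)
}

#' Write sequences as FASTA
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
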