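# Structure curation: a nine-step workflow turning raw SDF/SMILES inputs into
# a unique set of QSAR-ready structures keyed by standard InChI.
# Chemistry primitives (parsing, canonical SMILES, InChI, neutralization,
# formula/MW) are delegated to OpenBabel through ChemmineR/ChemmineOB; the
# workflow logic, filters, tautomer/mesomer rule engine and bookkeeping live
# here.

ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I")

# Maximum allowed total valence (sum of bond orders incl. explicit H) for the
# elements OpenBabel will happily over-bond. N = 5 admits the hypervalent
# neutral notation of nitro/azide groups (unified to the charge-separated
# mesomer later); other elements are unconstrained (hypervalent S/P are
# legitimate).
.MAX_VALENCE <- c(C = 4, N = 5, O = 3, F = 1, H = 1, B = 4)

.ob_quiet <- function(expr) {
  # OpenBabel chatters on stderr for benign normalizations; keep R-level
  # messages but swallow its warnings emitted through the R bridge.
  withCallingHandlers(expr, warning = function(w) invokeRestart("muffleWarning"))
}

.ob_convert1 <- function(smiles, to = "CAN", neutralize = FALSE) {
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else
    data.frame(names = character(), args = character())
  out <- tryCatch(
    .ob_quiet(ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\n"), options = opts)),
    error = function(e) NA_character_
  )
  if (is.na(out)) return(NA_character_)
  line <- strsplit(out, "\n", fixed = TRUE)[[1]]
  line <- line[nzchar(trimws(line))]
  if (length(line) == 0) return(NA_character_)
  tok <- strsplit(trimws(line[1]), "[ \t]+")[[1]]
  if (length(tok) == 0 || !nzchar(tok[1])) NA_character_ else tok[1]
}

#' Canonical SMILES via OpenBabel
#'
#' @param smiles character vector of SMILES strings.
#' @param neutralize apply OpenBabel's +1/-1 charge neutralization (hydrogen
#'   add/remove only; e.g. quaternary ammonium stays charged).
#' @return character vector of canonical SMILES, `NA` where conversion failed.
#' @export
canonical_smiles <- function(smiles, neutralize = FALSE) {
  vapply(smiles, .ob_convert1, character(1), to = "CAN", neutralize = neutralize,
         USE.NAMES = FALSE)
}

#' Standard InChI via OpenBabel
#' @param smiles character vector of SMILES strings.
#' @return character vector of standard InChI strings, `NA` on failure.
#' @export
structure_inchi <- function(smiles) {
  vapply(smiles, .ob_convert1, character(1), to = "INCHI", USE.NAMES = FALSE)
}

.sdf_from_smiles <- function(smiles) {
  tryCatch(.ob_quiet(suppressMessages(ChemmineR::smiles2sdf(stats::setNames(smiles, "m")))),
           error = function(e) NULL)
}

#' Molecular formula and weight
#'
#' @param smiles character vector of SMILES.
#' @return data.frame with columns `formula` and `molweight` (g/mol); NA rows
#'   where the structure could not be rendered.
#' @export
structure_properties <- function(smiles) {
  one <- function(s) {
    rep <- tryCatch(
      .ob_quiet(ChemmineOB::convertFormat("SMI", "report", paste0(s, "\n"))),
      error = function(e) NA_character_)
    if (is.na(rep)) return(c(NA_character_, NA_character_))
    lines <- strsplit(rep, "\n", fixed = TRUE)[[1]]
    grab <- function(key) {
      ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
      if (length(ln) == 0) NA_character_ else sub(paste0("^", key, ": "), "", ln[1])
    }
    c(grab("FORMULA"), grab("MASS"))
  }
  m <- vapply(smiles, one, character(2), USE.NAMES = FALSE)
  data.frame(formula = m[1, ], molweight = as.numeric(m[2, ]))
}

#' Parse a molecular formula into element counts
#' @param formula a Hill-notation molecular formula, e.g. `"C2H6O"`.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  el <- gsub("[0-9]", "", parts)
  n <- suppressWarnings(as.integer(gsub("[^0-9]", "", parts)))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)[unique(el)]
}

# ---- Step filters -----------------------------------------------------------

#' Keep/drop decision for inorganic structures
#'
#' A structure is dropped iff it contains no carbon atom.
#' @param formula molecular formula string(s).
#' @return logical vector, `TRUE` = keep.
#' @export
filter_inorganic <- function(formula) {
  vapply(formula, function(f) "C" %in% names(parse_formula(f)), logical(1),
         USE.NAMES = FALSE)
}

#' Keep/drop decision on molecular weight
#'
#' Drops structures strictly exceeding `max_mw` ("exceeding" is strict: a
#' structure at exactly the threshold is kept).
#' @param molweight numeric, g/mol.
#' @param max_mw threshold in g/mol (default 1000).
#' @return logical vector, `TRUE` = keep.
#' @export
filter_molweight <- function(molweight, max_mw = 1000) {
  molweight <= max_mw
}

#' Keep/drop decision on metal content
#'
#' Drops structures containing any atom outside the allowed organic element
#' set. By default the metalloids Si, Se and B (and the halogens, chalcogens
#' and pnictogens of common organic chemistry) are allowed; set
#' `keep_metalloids = FALSE` to also exclude Si/Se/B.
#' @param formula molecular formula string(s).
#' @param allowed_elements character vector of permitted element symbols.
#' @param keep_metalloids retain Si, Se and B (default TRUE).
#' @return logical vector, `TRUE` = keep.
#' @export
filter_metals <- function(formula, allowed_elements = ORGANIC_ELEMENTS,
                          keep_metalloids = TRUE) {
  if (!keep_metalloids) allowed_elements <- setdiff(allowed_elements, c("Si", "Se", "B"))
  vapply(formula, function(f) {
    el <- names(parse_formula(f))
    length(el) > 0 && all(el %in% allowed_elements)
  }, logical(1), USE.NAMES = FALSE)
}

# ---- Desalting --------------------------------------------------------------

#' Retain the largest organic fragment of a multi-component structure
#'
#' Fragments are ranked by (1) heavy-atom count, (2) molecular weight,
#' (3) lexicographically smallest canonical SMILES; only carbon-containing
#' fragments are eligible. Single-fragment input is returned unchanged.
#'
#' @param smiles a single SMILES string.
#' @return the SMILES of the retained fragment, or `NA` if no fragment is
#'   organic ("no organic fragment": the record is then dropped by the
#'   inorganic filter).
#' @export
desalt <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) <= 1) {
    return(if (length(frags) == 1) frags else NA_character_)
  }
  can <- canonical_smiles(frags)
  props <- structure_properties(can)
  organic <- !is.na(can) & filter_inorganic(props$formula)
  if (!any(organic)) return(NA_character_)
  heavy <- vapply(props$formula, function(f) {
    cnt <- parse_formula(f)
    sum(cnt[setdiff(names(cnt), "H")])
  }, numeric(1), USE.NAMES = FALSE)
  idx <- which(organic)
  idx <- idx[order(-heavy[idx], -props$molweight[idx], can[idx])]
  can[idx[1]]
}

# ---- Standardization --------------------------------------------------------

#' Remove stereochemistry descriptors from a SMILES string
#'
#' Strips tetrahedral (`@`) and double-bond (`/`, `\`) markers; the result is
#' re-canonicalized by the caller.
#' @param smiles character vector.
#' @return stereo-free SMILES.
#' @export
strip_stereo <- function(smiles) {
  s <- gsub("[/\\\\]", "", smiles)
  gsub("@", "", s, fixed = TRUE)
}

# Rewrite nitro and azide groups to their charge-separated canonical mesomer.
rewrite_mesomers <- function(smiles) {
  s <- gsub("N(=O)=O", "[N+](=O)[O-]", smiles, fixed = TRUE)
  s <- gsub("O=N(=O)", "O=[N+]([O-])", s, fixed = TRUE)
  s <- gsub("N=N=N", "N=[N+]=[N-]", s, fixed = TRUE)
  s
}

.has_charge_tokens <- function(smiles) {
  grepl("[+-]", gsub("\\[[0-9]*[A-Za-z@H]*([+-][0-9]*)?\\]", "", smiles)) ||
    grepl("[+-]", smiles)
}

# Atoms that belong to an aromatic ring (by ChemmineR's ring perception).
.aromatic_atoms <- function(mol) {
  r <- tryCatch(suppressWarnings(ChemmineR::rings(mol, type = "all", arom = TRUE)),
                error = function(e) NULL)
  if (is.null(r) || length(r$RINGS) == 0) return(character(0))
  arom <- r$AROMATIC
  unique(unlist(r$RINGS[which(arom)]))
}

#' Canonicalize tautomers with a fixed transform list
#'
#' Applies, to exhaustion and in a deterministic order, graph rewrites that
#' map each named tautomer class to a single representative: enol -> keto,
#' enamine -> imine, ynol -> ketene. Transforms never touch atoms of aromatic
#' rings (so phenols are fixed points) and are only attempted on charge-free
#' molecules; nitro/azide mesomers are handled separately at the SMILES level
#' and broader tautomer enumeration is deliberately out of scope.
#'
#' @param smiles a single (canonical, neutral) SMILES string.
#' @return list with `smiles` (possibly rewritten) and `rules` (character
#'   vector of rule names applied, empty if none).
#' @export
tautomer_canonicalize <- function(smiles) {
  if (.has_charge_tokens(smiles)) return(list(smiles = smiles, rules = character(0)))
  sdf <- .sdf_from_smiles(smiles)
  if (is.null(sdf)) return(list(smiles = smiles, rules = character(0)))
  mol <- sdf[[1]]
  applied <- character(0)
  for (iter in seq_len(25)) {
    ab <- ChemmineR::atomblock(mol)
    bb <- ChemmineR::bondblock(mol)
    if (!is.null(bb) && is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) > 0)
    if (is.null(bb) || nrow(ab) == 0 || length(bb) == 0 || nrow(bb) == 0 ||
        ncol(bb) < 3) break
    elem <- gsub("_.*$", "", rownames(ab))
    arom <- match(.aromatic_atoms(mol), rownames(ab))
    # per-atom heavy bond-order sum and degree
    n_at <- nrow(ab)
    bsum <- numeric(n_at); deg <- integer(n_at)
    for (k in seq_len(nrow(bb))) {
      a <- bb[k, 1]; b <- bb[k, 2]; o <- bb[k, 3]
      if (o == 4) o <- 1.5
      bsum[a] <- bsum[a] + o; bsum[b] <- bsum[b] + o
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    }
    bond_between <- function(a, b) which((bb[, 1] == a & bb[, 2] == b) |
                                           (bb[, 1] == b & bb[, 2] == a))[1]
    neighbors <- function(a) {
      k <- which(bb[, 1] == a | bb[, 2] == a)
      setdiff(unique(c(bb[k, 1], bb[k, 2])), a)
    }
    hit <- NULL
    # rule order: enol->keto, enamine->imine, ynol->ketene; lowest atom first
    for (o_at in which(elem == "O" & deg == 1 & bsum == 1)) {
      c1 <- neighbors(o_at)
      if (elem[c1] != "C" || (c1 %in% arom)) next
      for (c2 in neighbors(c1)) {
        bo <- bb[bond_between(c1, c2), 3]
        if (elem[c2] == "C" && !(c2 %in% arom)) {
          if (bo == 2) { hit <- list(rule = "enol_keto", o = o_at, c1 = c1, c2 = c2, triple = FALSE); break }
          if (bo == 3) { hit <- list(rule = "ynol_ketene", o = o_at, c1 = c1, c2 = c2, triple = TRUE); break }
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) {
      for (n_at_i in which(elem == "N" & bsum <= 2)) {   # N-H available
        if (n_at_i %in% arom) next
        for (c1 in neighbors(n_at_i)) {
          if (elem[c1] != "C" || (c1 %in% arom)) next
          if (bb[bond_between(n_at_i, c1), 3] != 1) next
          for (c2 in setdiff(neighbors(c1), n_at_i)) {
            if (elem[c2] == "C" && !(c2 %in% arom) &&
                bb[bond_between(c1, c2), 3] == 2) {
              hit <- list(rule = "enamine_imine", o = n_at_i, c1 = c1, c2 = c2, triple = FALSE)
              break
            }
          }
          if (!is.null(hit)) break
        }
        if (!is.null(hit)) break
      }
    }
    if (is.null(hit)) break
    kb1 <- bond_between(hit$o, hit$c1)
    kb2 <- bond_between(hit$c1, hit$c2)
    bb[kb1, 3] <- 2
    bb[kb2, 3] <- if (hit$triple) 2 else 1
    mol@bondblock <- bb
    applied <- c(applied, hit$rule)
  }
  if (length(applied) == 0) return(list(smiles = smiles, rules = character(0)))
  out <- tryCatch({
    smi <- .ob_quiet(suppressMessages(ChemmineR::sdf2smiles(
      methods::new("SDFset", SDF = list(mol), ID = "m"))))
    unname(as.character(smi)[1])
  }, error = function(e) NA_character_)
  if (is.na(out) || !nzchar(out)) return(list(smiles = smiles, rules = character(0)))
  list(smiles = out, rules = applied)
}

#' Standardize a single structure to QSAR-ready form
#'
#' Applies, in order: stereo descriptor removal, charge neutralization (where
#' possible by hydrogen addition/removal), nitro/azide mesomer unification,
#' tautomer canonicalization (fixed rule list), and re-canonicalization with
#' Hueckel aromaticity perception. Returns the canonical SMILES, the standard
#' InChI and the list of transformations that changed the structure.
#'
#' @param smiles a single SMILES string (already parsed/desalted).
#' @return list with `smiles`, `inchi`, `provenance` (character vector), or
#'   `NULL` if the structure did not survive sanitization.
#' @export
standardize_structure <- function(smiles) {
  prov <- character(0)
  s0 <- canonical_smiles(smiles)
  if (is.na(s0)) return(NULL)
  s1 <- strip_stereo(s0)
  if (!identical(s1, s0)) prov <- c(prov, "stereo_removed")
  s2 <- canonical_smiles(s1, neutralize = TRUE)
  if (is.na(s2)) return(NULL)
  if (!identical(s2, canonical_smiles(s1))) prov <- c(prov, "neutralized")
  s3 <- rewrite_mesomers(s2)
  if (!identical(s3, s2)) prov <- c(prov, "mesomer_unified")
  taut <- tautomer_canonicalize(s3)
  if (length(taut$rules) > 0) prov <- c(prov, unique(taut$rules))
  s4 <- canonical_smiles(taut$smiles)
  if (is.na(s4)) return(NULL)
  inchi <- structure_inchi(s4)
  if (is.na(inchi)) return(NULL)
  list(smiles = s4, inchi = inchi, provenance = prov)
}

# ---- Parsing ----------------------------------------------------------------

.valence_ok <- function(mol) {
  ab <- tryCatch(ChemmineR::atomblock(mol), error = function(e) NULL)
  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  if (is.null(ab)) return(FALSE)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) > 0)
  if (is.null(bb) || length(bb) == 0 || nrow(bb) == 0 || ncol(bb) < 3) {
    return(TRUE)
  }
  elem <- gsub("_.*$", "", rownames(ab))
  bsum <- numeric(nrow(ab))
  for (k in seq_len(nrow(bb))) {
    o <- bb[k, 3]
    if (o == 4) o <- 1.5
    bsum[bb[k, 1]] <- bsum[bb[k, 1]] + o
    bsum[bb[k, 2]] <- bsum[bb[k, 2]] + o
  }
  lim <- .MAX_VALENCE[elem]
  all(is.na(lim) | bsum <= lim)
}

#' Parse structures from an SDF or SMILES file
#'
#' Records failing to render a molecule or failing the valence check are
#' dropped and logged under `"invalid_structure"` (no external-database
#' structure repair is attempted).
#'
#' @param path input file path.
#' @param format `"sdf"` (V2000) or `"smiles"` (newline-delimited, optional
#'   whitespace-separated id as second token).
#' @return data.frame with columns `record_id`, `smiles`, `source`; dropped
#'   records are attached as attribute `"dropped"` (record_id, reason).
#' @export
parse_structures <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  ids <- character(0); smi <- character(0)
  dropped <- data.frame(record_id = character(0), reason = character(0))
  if (format == "smiles") {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    for (i in seq_along(lines)) {
      tok <- strsplit(lines[i], "[ \t]+")[[1]]
      id <- if (length(tok) >= 2) tok[2] else sprintf("rec%05d", i)
      can <- canonical_smiles(tok[1])
      ok <- !is.na(can)
      if (ok) {
        sdf <- .sdf_from_smiles(can)
        ok <- !is.null(sdf) && .valence_ok(sdf[[1]])
      }
      if (ok) { ids <- c(ids, id); smi <- c(smi, tok[1]) }
      else dropped <- rbind(dropped, data.frame(record_id = id, reason = "invalid_structure"))
    }
  } else {
    sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                       error = function(e) stop("unreadable SDF file: ", path))
    for (i in seq_along(sdfset)) {
      mol <- sdfset[[i]]
      id <- tryCatch({
        t <- ChemmineR::sdfid(sdfset[i])
        if (is.na(t) || !nzchar(t)) sprintf("sdf%05d", i) else t
      }, error = function(e) sprintf("sdf%05d", i))
      s <- tryCatch({
        if (!ChemmineR::validSDF(sdfset[i])) NA_character_ else {
          x <- .ob_quiet(suppressMessages(ChemmineR::sdf2smiles(sdfset[i])))
          as.character(x)[1]
        }
      }, error = function(e) NA_character_)
      ok <- !is.na(s) && nzchar(s) && .valence_ok(mol) && !is.na(canonical_smiles(s))
      if (ok) { ids <- c(ids, id); smi <- c(smi, s) }
      else dropped <- rbind(dropped, data.frame(record_id = id, reason = "invalid_structure"))
    }
  }
  if (length(ids) == 0) warning("no parseable records in ", path)
  out <- data.frame(record_id = ids, smiles = smi,
                    source = rep(path, length(ids)), stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

# ---- Full cascade -----------------------------------------------------------

#' Curate raw structure records into a unique QSAR-ready set
#'
#' Applies the full cascade in order: inorganic filter, desalting, molecular
#' weight filter, standardization (mesomer/tautomer unification,
#' neutralization, stereo removal, aromatization), InChI-based duplicate
#' merging, and the metal filter. Each record is removed at most once, logged
#' with the first step that triggered its removal.
#'
#' @param records data.frame with columns `record_id` and `smiles` (as
#'   returned by [parse_structures()]).
#' @param max_mw molecular weight cutoff in g/mol (default 1000; strictly
#'   greater-than removal).
#' @param keep_metalloids passed to [filter_metals()].
#' @return list with `structures` (data.frame: inchi, canonical_smiles,
#'   molweight, merged_ids, provenance) and `report` (see
#'   [curation_report()]).
#' @export
curate <- function(records, max_mw = 1000, keep_metalloids = TRUE) {
  removals <- c(invalid_structure = 0L, inorganic = 0L, molweight = 0L,
                standardization_failed = 0L, metal = 0L)
  corrections <- c(desalt = 0L, stereo_removed = 0L, neutralized = 0L,
                   mesomer_unified = 0L, enol_keto = 0L, enamine_imine = 0L,
                   ynol_ketene = 0L)
  log <- data.frame(record_id = character(0), step = character(0))
  n_input <- nrow(records)
  if (n_input == 0) {
    return(list(structures = .empty_curated(), report = curation_report(
      0L, 0L, removals, corrections, 0L, log)))
  }
  drop <- function(id, step) {
    removals[step] <<- removals[step] + 1L
    log <<- rbind(log, data.frame(record_id = id, step = step))
  }
  rows <- vector("list", n_input)
  for (i in seq_len(n_input)) {
    id <- records$record_id[i]
    can <- canonical_smiles(records$smiles[i])
    if (is.na(can)) { drop(id, "invalid_structure"); next }
    props <- structure_properties(can)
    if (is.na(props$formula[1]) || !filter_inorganic(props$formula[1])) {
      drop(id, "inorganic"); next
    }
    des <- desalt(can)
    if (is.na(des)) { drop(id, "inorganic"); next }
    desalted <- !identical(des, can)
    props <- structure_properties(des)
    if (is.na(props$molweight[1]) || !filter_molweight(props$molweight[1], max_mw)) {
      drop(id, "molweight"); next
    }
    std <- standardize_structure(des)
    if (is.null(std)) { drop(id, "standardization_failed"); next }
    prov <- std$provenance
    if (desalted) prov <- c("desalt", prov)
    for (p in prov) if (p %in% names(corrections))
      corrections[p] <- corrections[p] + 1L
    rows[[i]] <- data.frame(record_id = id, inchi = std$inchi,
                            canonical_smiles = std$smiles,
                            provenance = paste(prov, collapse = ";"),
                            stringsAsFactors = FALSE)
  }
  kept <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(kept) || nrow(kept) == 0) {
    return(list(structures = .empty_curated(), report = curation_report(
      n_input, 0L, removals, corrections, 0L, log)))
  }
  # InChI-based duplicate merging
  grp <- split(kept, kept$inchi)
  merged <- do.call(rbind, lapply(grp, function(g) {
    data.frame(inchi = g$inchi[1],
               canonical_smiles = g$canonical_smiles[1],
               merged_ids = paste(sort(g$record_id), collapse = ";"),
               provenance = paste(unique(unlist(strsplit(g$provenance, ";"))),
                                  collapse = ";"),
               n_records = nrow(g), stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$inchi), , drop = FALSE]
  n_merged_dups <- sum(merged$n_records - 1L)
  # metal filter (on unique structures)
  props <- structure_properties(merged$canonical_smiles)
  merged$molweight <- props$molweight
  keep <- filter_metals(props$formula, keep_metalloids = keep_metalloids)
  for (j in which(!keep)) {
    removals["metal"] <- removals["metal"] + 1L
    log <- rbind(log, data.frame(
      record_id = strsplit(merged$merged_ids[j], ";")[[1]][1], step = "metal"))
  }
  out <- merged[keep, c("inchi", "canonical_smiles", "molweight",
                        "merged_ids", "provenance"), drop = FALSE]
  rownames(out) <- NULL
  list(structures = out,
       report = curation_report(n_input, nrow(out), removals, corrections,
                                n_merged_dups, log))
}

.empty_curated <- function() {
  data.frame(inchi = character(0), canonical_smiles = character(0),
             molweight = numeric(0), merged_ids = character(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

#' Curation bookkeeping report
#'
#' Satisfies `n_input = n_output + sum(removals) + n_merged_duplicates`.
#' @param n_input,n_output record/structure counts.
#' @param removals named integer vector of per-filter removal counts.
#' @param corrections named integer vector of per-transformation counts.
#' @param n_merged_duplicates records absorbed into another structure.
#' @param log data.frame (record_id, step) of removals.
#' @return an object of class `curation_report`.
#' @export
curation_report <- function(n_input, n_output, removals, corrections,
                            n_merged_duplicates, log) {
  structure(list(n_input = n_input, n_output = n_output, removals = removals,
                 corrections = corrections,
                 n_merged_duplicates = n_merged_duplicates, log = log),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Structure curation report\n")
  cat(sprintf("  input records : %d\n  output structures: %d\n", x$n_input, x$n_output))
  cat(sprintf("  merged duplicates: %d\n", x$n_merged_duplicates))
  cat("  removals:\n")
  for (nm in names(x$removals)) if (x$removals[nm] > 0)
    cat(sprintf("    %-24s %d\n", nm, x$removals[nm]))
  invisible(x)
}

#' Write curated structures to disk
#'
#' Emits a QSAR-ready SDF, a delimited structure table and a per-step count
#' report file.
#' @param curated result of [curate()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_curated <- function(curated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- curated$structures
  tab_path <- file.path(dir, "curated_structures.tsv")
  utils::write.table(st, tab_path, sep = "\t", row.names = FALSE, quote = FALSE)
  sdf_path <- file.path(dir, "curated_structures.sdf")
  if (nrow(st) > 0) {
    sdf <- .ob_quiet(suppressMessages(ChemmineR::smiles2sdf(
      stats::setNames(st$canonical_smiles, st$inchi))))
    ChemmineR::write.SDF(sdf, sdf_path)
  } else file.create(sdf_path)
  rep_path <- file.path(dir, "curation_report.tsv")
  r <- curated$report
  utils::write.table(
    data.frame(step = c("input", "output", "merged_duplicates",
                        names(r$removals)),
               count = c(r$n_input, r$n_output, r$n_merged_duplicates,
                         unname(r$removals))),
    rep_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(tab_path, sdf_path, rep_path))
}
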