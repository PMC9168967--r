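# Glycan structure model: four core motifs plus a configurable antenna
# library. A structure is a rooted tree summarised as (core kind, multiset of
# branch motifs); branch-internal topology is carried by the library rows.

.glyco_cache <- new.env(parent = emptyenv())

#' The four N-glycan core motifs
#'
#' The trimannosyl-chitobiose core HexNAc2Hex3, optionally carrying a core
#' fucose on the innermost GlcNAc and/or a bisecting GlcNAc on the branching
#' mannose.
#'
#' @return Tibble with columns `kind` and `composition` (string form).
#' @export
core_motifs <- function() {
  tibble::tibble(
    kind = c("plain", "core_fucosylated", "bisecting", "fucosylated_bisecting"),
    composition = c("N2H3", "N2H3F1", "N3H3", "N3H3F1")
  )
}

#' Load a branch motif library
#'
#' Reads a YAML motif library (defaulting to the 12-motif library shipped
#' with the package) and derives each motif's composition and residue mass.
#' A LacdiNAc-family motif contains two consecutive HexNAc residues
#' (GalNAc-GlcNAc); a LacNAc-family motif contains HexNAc-Hex.
#'
#' @param path Optional path to a YAML library file.
#' @return Tibble with columns `name`, `family`, `chain` (list), `decorations`
#'   (list), `composition` (string) and `mass` (Da).
#' @export
default_branch_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "branch_library.yaml", package = "glycostruct")
  }
  raw <- yaml::read_yaml(path)$branches
  lib <- purrr::map_dfr(raw, function(b) {
    residues <- c(unlist(b$chain), unlist(b$decorations))
    comp <- comp_from_residues(residues)
    tibble::tibble(
      name = b$name, family = b$family,
      chain = list(unlist(b$chain)),
      decorations = list(if (is.null(b$decorations)) character() else unlist(b$decorations)),
      composition = serialize_composition(comp),
      mass = composition_mass(comp)
    )
  })
  stopifnot(!anyDuplicated(lib$name))
  lib
}

comp_from_residues <- function(residues) {
  glycan_comp(sum(residues == "HexNAc"), sum(residues == "Hex"),
              sum(residues == "Fuc"), sum(residues == "NeuAc"))
}

lib_row <- function(library, name) {
  i <- match(name, library$name)
  if (is.na(i)) stop("unknown branch motif ", sQuote(name), call. = FALSE)
  library[i, ]
}

#' Construct a glycan structure
#'
#' @param core Core kind, one of `core_motifs()$kind`.
#' @param branches Character vector of branch motif names (a multiset; order
#'   is irrelevant and the canonical form sorts it).
#' @param library Branch library tibble, see [default_branch_library()].
#' @param max_antennae Cap on HexNAc-initiated antennae (default 4).
#' @return A `glycan_structure` object with fields `core`, `branches`,
#'   `canonical` and `composition`.
#' @examples
#' lib <- default_branch_library()
#' gs <- glycan_structure("core_fucosylated", c("LacdiNAc+NeuAc", "LacNAc"), lib)
#' gs$canonical
#' @export
glycan_structure <- function(core, branches = character(), library = default_branch_library(),
                             max_antennae = 4L) {
  cores <- core_motifs()
  if (!core %in% cores$kind) stop("unknown core kind ", sQuote(core), call. = FALSE)
  branches <- sort(as.character(branches))
  fams <- purrr::map_chr(branches, ~ lib_row(library, .x)$family)
  if (sum(fams != "Mannose") > max_antennae) {
    stop("more than ", max_antennae, " non-mannose antennae", call. = FALSE)
  }
  comp <- parse_composition(cores$composition[cores$kind == core])
  for (b in branches) {
    comp <- comp_add(comp, parse_composition(lib_row(library, b)$composition))
  }
  structure(
    list(core = core, branches = branches,
         canonical = paste0(core, "(", paste(branches, collapse = ","), ")"),
         composition = comp),
    class = "glycan_structure"
  )
}

#' @export
print.glycan_structure <- function(x, ...) {
  cat("<glycan structure> ", x$canonical, "  [",
      serialize_composition(x$composition), "]\n", sep = "")
  invisible(x)
}

#' @rdname glycan_structure
#' @param text Canonical structure string, e.g.
#'   `"core_fucosylated(LacNAc,LacdiNAc+NeuAc)"`.
#' @export
parse_structure <- function(text, library = default_branch_library()) {
  m <- stringr::str_match(text, "^([a-z_]+)\\(([^)]*)\\)$")
  if (is.na(m[1, 1])) stop("malformed structure string: ", sQuote(text), call. = FALSE)
  branches <- if (nzchar(m[1, 3])) strsplit(m[1, 3], ",", fixed = TRUE)[[1]] else character()
  glycan_structure(m[1, 2], branches, library)
}

#' @rdname glycan_structure
#' @param structure A `glycan_structure`.
#' @export
structure_composition <- function(structure) structure$composition

#' Enumerate all structures consistent with a composition
#'
#' Exhaustively generates every (core kind, branch multiset) assembly from
#' the library whose summed composition equals `comp` exactly, deduplicated
#' under the canonical encoding. A composition smaller than every core
#' yields an empty set.
#'
#' @param comp A [glycan_comp()] or composition string.
#' @param library Branch library tibble.
#' @param max_antennae Cap on HexNAc-initiated antennae (default 4).
#' @param max_mannose Cap on mannose-family branches (default 6, enough for
#'   Man9 assemblies).
#' @return List of `glycan_structure` objects.
#' @examples
#' length(enumerate_structures("N4H5F1")) # >= 7 isomeric assemblies
#' @export
enumerate_structures <- function(comp, library = default_branch_library(),
                                 max_antennae = 4L, max_mannose = 6L) {
  if (is.character(comp)) comp <- parse_composition(comp)
  key <- paste0("enum:", serialize_composition(comp), ":", nrow(library),
                ":", max_antennae, ":", max_mannose)
  if (!is.null(.glyco_cache[[key]])) return(.glyco_cache[[key]])

  cores <- core_motifs()
  branch_comps <- lapply(library$composition, parse_composition)
  is_antenna <- library$family != "Mannose"
  out <- list()

  recurse <- function(i, residual, counts, n_ant, n_man) {
    total <- sum(residual)
    if (total == 0) {
      out[[length(out) + 1L]] <<- counts
      return(invisible())
    }
    if (i > nrow(library)) return(invisible())
    bc <- branch_comps[[i]]
    max_k <- if (sum(bc) > 0) total %/% sum(bc) else 0L
    for (k in 0:max_k) {
      if (is_antenna[i] && n_ant + k > max_antennae) break
      if (!is_antenna[i] && n_man + k > max_mannose) break
      res_k <- residual
      ok <- TRUE
      if (k > 0) {
        for (j in seq_len(k)) {
          nxt <- comp_subtract(res_k, bc)
          if (is.null(nxt)) { ok <- FALSE; break }
          res_k <- nxt
        }
      }
      if (!ok) break
      counts_k <- counts
      counts_k[i] <- k
      recurse(i + 1L, res_k,
              counts_k,
              n_ant + if (is_antenna[i]) k else 0L,
              n_man + if (!is_antenna[i]) k else 0L)
    }
  }

  structures <- list()
  for (ci in seq_len(nrow(cores))) {
    ccomp <- parse_composition(cores$composition[ci])
    residual <- comp_subtract(comp, ccomp)
    if (is.null(residual)) next
    out <- list()
    recurse(1L, residual, integer(nrow(library)), 0L, 0L)
    for (counts in out) {
      branches <- rep(library$name, counts)
      structures[[length(structures) + 1L]] <-
        glycan_structure(cores$kind[ci], branches, library, max_antennae)
    }
  }
  canon <- purrr::map_chr(structures, "canonical")
  structures <- structures[!duplicated(canon)]
  .glyco_cache[[key]] <- structures
  structures
}

# All B-ion fragment compositions of one branch motif: every contiguous
# sub-chain of the residue chain, with the root Fuc attached to fragments
# containing the root and the terminal NeuAc attached to fragments containing
# the tip (plus the bare NeuAc oxonium for sialylated motifs).
branch_b_fragments <- function(branch_row) {
  chain <- branch_row$chain[[1]]
  dec <- branch_row$decorations[[1]]
  has_fuc <- "Fuc" %in% dec
  has_sia <- "NeuAc" %in% dec
  n <- length(chain)
  frags <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      base <- comp_from_residues(chain[i:j])
      frags[[length(frags) + 1L]] <- base
      if (has_fuc && i == 1L) {
        frags[[length(frags) + 1L]] <- comp_add(base, glycan_comp(Fuc = 1))
      }
      if (has_sia && j == n) {
        frags[[length(frags) + 1L]] <- comp_add(base, glycan_comp(NeuAc = 1))
      }
      if (has_fuc && has_sia && i == 1L && j == n) {
        frags[[length(frags) + 1L]] <-
          comp_add(base, glycan_comp(Fuc = 1, NeuAc = 1))
      }
    }
  }
  if (has_sia) frags[[length(frags) + 1L]] <- glycan_comp(NeuAc = 1)
  frags
}

#' Theoretical glycan B ions of a structure
#'
#' For each branch motif the full decorated oxonium and all contiguous
#' sub-fragments are generated (so a sialylated LacdiNAc yields HexNAc2 at
#' 407.17, HexNAc1NeuAc1 at 495.18 and HexNAc2NeuAc1 at 698.26), plus the
#' single-residue HexNAc and Hex oxonium ions contributed by the core.
#' Singly charged, deduplicated by composition, sorted by m/z.
#'
#' @param structure A `glycan_structure`.
#' @param library Branch library tibble.
#' @return Tibble with columns `composition` and `mz`.
#' @export
theoretical_b_ions <- function(structure, library = default_branch_library()) {
  key <- paste0("bion:", structure$canonical)
  if (!is.null(.glyco_cache[[key]])) return(.glyco_cache[[key]])
  frags <- list(glycan_comp(HexNAc = 1), glycan_comp(Hex = 1))
  for (b in structure$branches) {
    frags <- c(frags, branch_b_fragments(lib_row(library, b)))
  }
  tab <- tibble::tibble(
    composition = purrr::map_chr(frags, serialize_composition),
    mz = purrr::map_dbl(frags, oxonium_mz)
  )
  tab <- dplyr::arrange(dplyr::distinct(tab), .data$mz)
  .glyco_cache[[key]] <- tab
  tab
}

# Retained-glycan composition options for one branch under terminal pruning:
# prefixes of the chain outward from the root (the NeuAc cap only together
# with the full chain, the root Fuc with any non-empty prefix).
branch_y_prefixes <- function(branch_row) {
  chain <- branch_row$chain[[1]]
  dec <- branch_row$decorations[[1]]
  has_fuc <- "Fuc" %in% dec
  has_sia <- "NeuAc" %in% dec
  opts <- list(glycan_comp())
  for (j in seq_along(chain)) {
    base <- comp_from_residues(chain[1:j])
    opts[[length(opts) + 1L]] <- base
    if (has_fuc) opts[[length(opts) + 1L]] <- comp_add(base, glycan_comp(Fuc = 1))
    if (has_sia && j == length(chain)) {
      opts[[length(opts) + 1L]] <- comp_add(base, glycan_comp(NeuAc = 1))
      if (has_fuc) {
        opts[[length(opts) + 1L]] <- comp_add(base, glycan_comp(Fuc = 1, NeuAc = 1))
      }
    }
  }
  opts
}

# Retained-glycan compositions (as serialized strings) for the whole
# structure: the core Y ladder plus the full core with every combination of
# branch prefixes, with core-fucose / bisecting variants where applicable.
structure_y_compositions <- function(structure, library = default_branch_library()) {
  key <- paste0("ycomp:", structure$canonical)
  if (!is.null(.glyco_cache[[key]])) return(.glyco_cache[[key]])
  has_fuc <- structure$core %in% c("core_fucosylated", "fucosylated_bisecting")
  has_bis <- structure$core %in% c("bisecting", "fucosylated_bisecting")

  ladder <- list(glycan_comp(), glycan_comp(HexNAc = 1), glycan_comp(HexNAc = 2),
                 glycan_comp(HexNAc = 2, Hex = 1), glycan_comp(HexNAc = 2, Hex = 2),
                 glycan_comp(HexNAc = 2, Hex = 3))
  if (has_fuc) {
    ladder <- c(ladder, purrr::map(ladder[-1], comp_add, glycan_comp(Fuc = 1)))
  }
  core_full <- list(glycan_comp(HexNAc = 2, Hex = 3))
  if (has_fuc) core_full <- c(core_full, purrr::map(core_full, comp_add, glycan_comp(Fuc = 1)))
  if (has_bis) core_full <- c(core_full, purrr::map(core_full, comp_add, glycan_comp(HexNAc = 1)))

  combos <- core_full
  for (b in structure$branches) {
    opts <- branch_y_prefixes(lib_row(library, b))
    combos <- purrr::flatten(purrr::map(combos, function(base) {
      purrr::map(opts, comp_add, base)
    }))
  }
  all_comps <- c(ladder, combos)
  keys <- purrr::map_chr(all_comps, serialize_composition)
  res <- tibble::tibble(
    composition = keys,
    glycan_mass = purrr::map_dbl(all_comps, composition_mass)
  )
  res <- dplyr::distinct(res, .data$composition, .keep_all = TRUE)
  .glyco_cache[[key]] <- res
  res
}

#' Theoretical glycan Y ions of a glycopeptide
#'
#' Y ions retain the peptide plus a connected remnant of the glycan obtained
#' by pruning branches terminally. The set always includes Y0 (bare
#' peptide), Y1 (peptide+HexNAc), the chitobiose/trimannosyl core ladder,
#' the Fuc-shifted ladder for core-fucosylated structures, and the full core
#' with every combination of branch root-prefixes.
#'
#' @param structure A `glycan_structure`.
#' @param peptide_mass Neutral peptide mass in Da (including static
#'   modifications), must be positive.
#' @param charges Integer vector of charge states (subset of 1..4).
#' @param library Branch library tibble.
#' @return Tibble with columns `composition`, `charge`, `mz`.
#' @export
theoretical_y_ions <- function(structure, peptide_mass, charges = 1:2,
                               library = default_branch_library()) {
  if (!is.numeric(peptide_mass) || peptide_mass <= 0) {
    stop("peptide_mass must be positive", call. = FALSE)
  }
  charges <- sort(unique(as.integer(charges)))
  stopifnot(all(charges >= 1), all(charges <= 4))
  comps <- structure_y_compositions(structure, library)
  out <- purrr::map_dfr(charges, function(z) {
    tibble::tibble(
      composition = comps$composition,
      charge = z,
      mz = (peptide_mass + comps$glycan_mass + z * PROTON_MASS) / z
    )
  })
  dplyr::arrange(out, .data$mz)
}

#' Structural feature vector of a glycan
#'
#' Derives the reporting features used in the differential summaries:
#' glycan subtype (oligo-mannose / hybrid / complex), core kind, fucose and
#' sialic-acid counts, antenna count, and flags for LacdiNAc branches, core
#' fucose, bisecting GlcNAc and antenna fucose. Fucose location flags come
#' from the structure, not the composition.
#'
#' @param structure A `glycan_structure`.
#' @param library Branch library tibble.
#' @return One-row tibble.
#' @export
classify_features <- function(structure, library = default_branch_library()) {
  fams <- purrr::map_chr(structure$branches, ~ lib_row(library, .x)$family)
  decs <- purrr::map(structure$branches, ~ lib_row(library, .x)$decorations[[1]])
  comp <- structure$composition
  has_bis <- structure$core %in% c("bisecting", "fucosylated_bisecting")
  has_cf <- structure$core %in% c("core_fucosylated", "fucosylated_bisecting")
  n_ant <- sum(fams != "Mannose")
  has_sia <- any(purrr::map_lgl(decs, ~ "NeuAc" %in% .x))
  subtype <- if (all(fams == "Mannose") && !has_bis && !has_sia) {
    "oligo_mannose"
  } else if (n_ant == length(fams)) {
    "complex"
  } else {
    "hybrid"
  }
  tibble::tibble(
    subtype = subtype,
    core_kind = structure$core,
    n_fucose = comp[["Fuc"]],
    n_sialic = comp[["NeuAc"]],
    n_antennae = n_ant,
    has_lacdinac = any(fams == "LacdiNAc"),
    has_core_fucose = has_cf,
    has_bisecting = has_bis,
    antenna_fucose = any(purrr::map_lgl(decs, ~ "Fuc" %in% .x))
  )
}
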