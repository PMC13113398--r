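#' Read a protein structure into an atom table
#'
#' Parses fixed-column PDB-format coordinates (via bio3d) into a tidy atom
#' table. Waters are excluded by default; alternate locations keep the blank
#' or `'A'` indicator, falling back to the first indicator present for
#' residues that have no blank/'A' atoms; only the first MODEL of a
#' multi-model file is used. Missing element symbols are inferred from the
#' atom name (leading digits stripped; `1HB` is hydrogen, `CA` carbon, and
#' so on).
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param chains Optional chain identifiers to keep; an empty selection is
#'   an error.
#' @param keep_waters Keep HOH/WAT residues?
#' @return A tibble with columns `serial`, `atom`, `altloc`, `resname`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `element`.
#' @export
read_structure <- function(pdb, chains = NULL, keep_waters = FALSE) {
  if (length(pdb) > 1 || grepl("\n", pdb[1], fixed = TRUE) ||
      !file.exists(pdb[1])) {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
  } else {
    path <- pdb
  }
  parsed <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("malformed PDB input: ", conditionMessage(e),
                             call. = FALSE)
  )
  a <- parsed$atom
  at <- tibble::tibble(
    serial = a$eleno, atom = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = a$resid, chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    element = ifelse(is.na(a$elesy) | a$elesy == "", "", trimws(a$elesy))
  )
  if (!keep_waters) at <- at[!at$resname %in% c("HOH", "WAT", "DOD"), ]
  if (!is.null(chains)) {
    at <- at[at$chain %in% chains, ]
    if (nrow(at) == 0) {
      stop("empty chain selection: no atoms in chain(s) ",
           paste(chains, collapse = ", "), call. = FALSE)
    }
  }
  # altloc: keep blank/'A'; for residues represented only by other
  # indicators, keep the lexicographically first one present
  res_key <- paste(at$chain, at$resno, at$insert, at$resname)
  keep <- at$altloc %in% c("", " ", "A")
  for (rk in unique(res_key[!keep])) {
    rows <- which(res_key == rk)
    if (!any(keep[rows])) {
      first_alt <- sort(unique(at$altloc[rows]))[1]
      keep[rows[at$altloc[rows] == first_alt]] <- TRUE
    }
  }
  at <- at[keep, ]
  need <- at$element == ""
  at$element[need] <- infer_element(at$atom[need])
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("non-finite coordinates in PDB input", call. = FALSE)
  }
  at
}

infer_element <- function(atom_name) {
  nm <- gsub("^[0-9]+", "", trimws(atom_name))
  el <- substr(nm, 1, 1)
  # two-letter elements common in structures
  two <- toupper(substr(nm, 1, 2))
  el[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "SE")]
  el
}

#' Serialize an atom table to PDB-format lines
#'
#' Writes fixed-column ATOM records from an atom table in the layout of
#' [read_structure()]. Intended for building small synthetic coordinate
#' fixtures in code.
#'
#' @param atoms Atom tibble (columns as returned by [read_structure()]).
#' @return Character vector of PDB lines (terminated by `END`).
#' @export
as_pdb_lines <- function(atoms) {
  name4 <- function(atom, element) {
    # element right-aligned in cols 13-14 per PDB convention
    ifelse(nchar(element) == 1 & nchar(atom) <= 3,
           sprintf(" %-3s", atom), sprintf("%-4s", atom))
  }
  lines <- sprintf(
    "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$serial, name4(atoms$atom, atoms$element),
    ifelse(atoms$altloc == "", " ", atoms$altloc),
    atoms$resname, ifelse(atoms$chain == "", " ", atoms$chain), atoms$resno,
    ifelse(atoms$insert == "", " ", atoms$insert),
    atoms$x, atoms$y, atoms$z, 1.00, 0.00, atoms$element
  )
  c(lines, "END")
}

#' Interface residue contacts between two molecules
#'
#' A residue pair is a contact when any cross-molecule atom pair lies within
#' the distance cutoff (4.0 Angstrom by default, polar and nonpolar atoms
#' alike). The minimal interatomic distance and the closest atom pair are
#' reported per residue pair; a pair whose closest atoms are both carbon or
#' sulfur is classified `nonpolar` (a hydrophobic contact), anything
#' involving nitrogen or oxygen `polar`.
#'
#' The default neighbour search bins atoms into a spatial grid of
#' cutoff-sized cells and compares adjacent cells only; it returns exactly
#' the same contact set as the exhaustive all-pairs scan
#' (`method = "all_pairs"`), which is retained as a cross-check.
#'
#' @param receptor,ligand Atom tibbles from [read_structure()] (non-empty).
#' @param cutoff Contact distance cutoff, Angstrom (> 0).
#' @param method `"grid"` (default) or `"all_pairs"`.
#' @return A tibble with one row per contacting residue pair:
#'   `receptor_res`, `ligand_res`, `min_dist`, `receptor_atom`,
#'   `ligand_atom`, `class`.
#' @export
find_contacts <- function(receptor, ligand, cutoff = 4.0,
                          method = c("grid", "all_pairs")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("`cutoff` must be > 0", call. = FALSE)
  if (nrow(receptor) == 0 || nrow(ligand) == 0) {
    stop("both atom tables must be non-empty", call. = FALSE)
  }
  pairs <- if (method == "grid") {
    grid_pairs(receptor, ligand, cutoff)
  } else {
    all_pairs(receptor, ligand, cutoff)
  }
  if (nrow(pairs) == 0) {
    return(tibble::tibble(receptor_res = character(), ligand_res = character(),
                          min_dist = numeric(), receptor_atom = character(),
                          ligand_atom = character(), class = character()))
  }
  pairs$receptor_res <- res_label(receptor[pairs$i, ])
  pairs$ligand_res <- res_label(ligand[pairs$j, ])
  pairs$receptor_atom <- receptor$atom[pairs$i]
  pairs$ligand_atom <- ligand$atom[pairs$j]
  pairs$el_r <- receptor$element[pairs$i]
  pairs$el_l <- ligand$element[pairs$j]
  pairs |>
    dplyr::group_by(.data$receptor_res, .data$ligand_res) |>
    dplyr::slice_min(.data$dist, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      class = ifelse(.data$el_r %in% c("C", "S") & .data$el_l %in% c("C", "S"),
                     "nonpolar", "polar")
    ) |>
    dplyr::select("receptor_res", "ligand_res", min_dist = "dist",
                  "receptor_atom", "ligand_atom", "class") |>
    dplyr::arrange(.data$receptor_res, .data$ligand_res)
}

res_label <- function(at) {
  paste0(ifelse(at$chain == "", "_", at$chain), ":", at$resname,
         at$resno, at$insert)
}

# exhaustive cross-molecule pair scan
all_pairs <- function(a, b, cutoff) {
  dx <- outer(a$x, b$x, "-")
  dy <- outer(a$y, b$y, "-")
  dz <- outer(a$z, b$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  idx <- which(d <= cutoff, arr.ind = TRUE)
  tibble::tibble(i = idx[, 1], j = idx[, 2], dist = d[idx])
}

# cell-grid pruned pair scan; exact (cells are cutoff-sized, 27-neighbourhood)
grid_pairs <- function(a, b, cutoff) {
  key <- function(cx, cy, cz) paste(cx, cy, cz)
  cb <- list(x = floor(b$x / cutoff), y = floor(b$y / cutoff),
             z = floor(b$z / cutoff))
  b_bins <- split(seq_len(nrow(b)), key(cb$x, cb$y, cb$z))
  ca <- list(x = floor(a$x / cutoff), y = floor(a$y / cutoff),
             z = floor(a$z / cutoff))
  off <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1)
  out <- vector("list", nrow(a))
  for (ii in seq_len(nrow(a))) {
    neigh <- unlist(b_bins[key(ca$x[ii] + off$ox, ca$y[ii] + off$oy,
                               ca$z[ii] + off$oz)], use.names = FALSE)
    if (is.null(neigh) || length(neigh) == 0) next
    d <- sqrt((a$x[ii] - b$x[neigh])^2 + (a$y[ii] - b$y[neigh])^2 +
                (a$z[ii] - b$z[neigh])^2)
    hit <- d <= cutoff
    if (any(hit)) {
      out[[ii]] <- tibble::tibble(i = ii, j = neigh[hit], dist = d[hit])
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) tibble::tibble(i = integer(), j = integer(),
                                     dist = numeric())
  else res
}

#' Hydrogen bonds across a protein-protein interface
#'
#' Donors are nitrogen or oxygen atoms carrying a covalently bonded hydrogen
#' (any hydrogen within 1.25 Angstrom in the same residue); acceptors are
#' nitrogens or oxygens of the other molecule. Under the default geometric
#' criteria a bond requires donor-acceptor distance <= `d_da_max`,
#' hydrogen-acceptor distance <= `d_ha_max` and donor-hydrogen-acceptor
#' angle >= `angle_min`. With `report_all = TRUE` every candidate
#' donor-acceptor pair up to `da_scan` Angstrom is listed with its geometry
#' and no criterion applied — useful for reproducing published distance
#' tables that include out-of-convention pairs. Structures without hydrogens
#' fall back, with a warning, to the donor-acceptor distance criterion
#' alone.
#'
#' @param receptor,ligand Atom tibbles from [read_structure()].
#' @param d_da_max,d_ha_max,angle_min Geometric criteria (Angstrom,
#'   Angstrom, degrees).
#' @param report_all List all candidate pairs within `da_scan` instead of
#'   applying the criteria.
#' @param da_scan Donor-acceptor scan radius for `report_all`, Angstrom.
#' @return A tibble: `donor_res`, `donor_atom`, `acceptor_res`,
#'   `acceptor_atom`, `d_da`, `d_ha`, `angle`, `donor_molecule`.
#' @export
find_hbonds <- function(receptor, ligand, d_da_max = 3.5, d_ha_max = 2.7,
                        angle_min = 120, report_all = FALSE, da_scan = 5.5) {
  scan <- if (report_all) da_scan else d_da_max
  have_h <- any(receptor$element == "H") || any(ligand$element == "H")
  if (!have_h && !report_all) {
    warning("no hydrogens present: applying the donor-acceptor distance ",
            "criterion only", call. = FALSE)
  }
  one_direction <- function(don_mol, acc_mol, label) {
    don <- don_mol[don_mol$element %in% c("N", "O"), , drop = FALSE]
    acc <- acc_mol[acc_mol$element %in% c("N", "O"), , drop = FALSE]
    if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    hyd <- don_mol[don_mol$element == "H", , drop = FALSE]
    pairs <- all_pairs(don, acc, scan)
    if (nrow(pairs) == 0) return(NULL)
    rows <- purrr::pmap(pairs, function(i, j, dist) {
      d_at <- don[i, ]; a_at <- acc[j, ]
      # hydrogens bonded to this donor
      hd <- hyd[hyd$chain == d_at$chain & hyd$resno == d_at$resno &
                  hyd$insert == d_at$insert, , drop = FALSE]
      d_ha <- NA_real_; ang <- NA_real_
      if (nrow(hd) > 0) {
        dh <- sqrt((hd$x - d_at$x)^2 + (hd$y - d_at$y)^2 + (hd$z - d_at$z)^2)
        hd <- hd[dh <= 1.25, , drop = FALSE]
        if (nrow(hd) > 0) {
          ha <- sqrt((hd$x - a_at$x)^2 + (hd$y - a_at$y)^2 +
                       (hd$z - a_at$z)^2)
          k <- which.min(ha)
          d_ha <- ha[k]
          ang <- dha_angle(d_at, hd[k, ], a_at)
        }
      }
      tibble::tibble(donor_res = res_label(d_at), donor_atom = d_at$atom,
                     acceptor_res = res_label(a_at),
                     acceptor_atom = a_at$atom,
                     d_da = dist, d_ha = d_ha, angle = ang,
                     donor_molecule = label)
    })
    dplyr::bind_rows(rows)
  }
  cand <- dplyr::bind_rows(one_direction(receptor, ligand, "receptor"),
                           one_direction(ligand, receptor, "ligand"))
  if (is.null(cand)) cand <- tibble::tibble()
  # without the hydrogen criterion the donor orientation is ambiguous:
  # keep each unordered atom pair once
  dedupe <- function(x) {
    if (nrow(x) == 0) return(x)
    a <- paste(x$donor_res, x$donor_atom)
    b <- paste(x$acceptor_res, x$acceptor_atom)
    x[!duplicated(paste(pmin(a, b), pmax(a, b))), , drop = FALSE]
  }
  if (nrow(cand) == 0 || report_all) {
    return(dedupe(cand))
  }
  if (!have_h) {
    return(dedupe(cand[cand$d_da <= d_da_max, , drop = FALSE]))
  }
  # geometric criteria: donors must actually carry a hydrogen
  ok <- !is.na(cand$d_ha) & cand$d_da <= d_da_max &
    cand$d_ha <= d_ha_max & cand$angle >= angle_min
  cand[ok, , drop = FALSE]
}

dha_angle <- function(d_at, h_at, a_at) {
  u <- c(d_at$x - h_at$x, d_at$y - h_at$y, d_at$z - h_at$z)
  v <- c(a_at$x - h_at$x, a_at$y - h_at$y, a_at$z - h_at$z)
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Salt bridges across a protein-protein interface
#'
#' Reports pairs between basic side-chain nitrogens (Lys NZ; Arg NE, NH1,
#' NH2; His ND1, NE2) of one molecule and acidic side-chain oxygens (Asp
#' OD1/OD2; Glu OE1/OE2; any terminal OXT) of the other within the cutoff,
#' in both orientations.
#'
#' @param receptor,ligand Atom tibbles from [read_structure()].
#' @param cutoff Distance cutoff, Angstrom.
#' @return A tibble: `basic_res`, `basic_atom`, `acidic_res`, `acidic_atom`,
#'   `dist`, `basic_molecule`.
#' @export
find_salt_bridges <- function(receptor, ligand, cutoff = 4.0) {
  is_basic <- function(at) {
    (at$resname == "LYS" & at$atom == "NZ") |
      (at$resname == "ARG" & at$atom %in% c("NE", "NH1", "NH2")) |
      (at$resname == "HIS" & at$atom %in% c("ND1", "NE2"))
  }
  is_acidic <- function(at) {
    (at$resname == "ASP" & at$atom %in% c("OD1", "OD2")) |
      (at$resname == "GLU" & at$atom %in% c("OE1", "OE2")) |
      at$atom == "OXT"
  }
  one <- function(mol_b, mol_a, label) {
    b <- mol_b[is_basic(mol_b), , drop = FALSE]
    a <- mol_a[is_acidic(mol_a), , drop = FALSE]
    if (nrow(b) == 0 || nrow(a) == 0) return(NULL)
    pairs <- all_pairs(b, a, cutoff)
    if (nrow(pairs) == 0) return(NULL)
    tibble::tibble(basic_res = res_label(b[pairs$i, ]),
                   basic_atom = b$atom[pairs$i],
                   acidic_res = res_label(a[pairs$j, ]),
                   acidic_atom = a$atom[pairs$j],
                   dist = pairs$dist, basic_molecule = label)
  }
  out <- dplyr::bind_rows(one(receptor, ligand, "receptor"),
                          one(ligand, receptor, "ligand"))
  if (is.null(out)) tibble::tibble() else out
}
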