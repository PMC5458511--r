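#' Read an atomic model as a tidy atom table
#'
#' Reads PDB or mmCIF (via bio3d) into the tabular atomic-model
#' representation used by the B-factor and ring-geometry analyses: one row
#' per atom with chain, residue number and name, atom name, element,
#' coordinates (Angstrom), B-factor (Angstrom squared) and occupancy.
#'
#' @param path a `.pdb` or `.cif` file.
#' @return A tibble of class `atomic_model`, ordered by chain and residue
#'   number.
#' @export
read_model <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- switch(ext,
    pdb = bio3d::read.pdb(path),
    cif = suppressWarnings(bio3d::read.cif(path)),
    stop("unsupported model format '.", ext, "' (use .pdb or .cif)",
         call. = FALSE))
  atomic_model(tibble::tibble(
    chain = pdb$atom$chain, resno = pdb$atom$resno, resname = pdb$atom$resid,
    atom = pdb$atom$elety, element = pdb$atom$elesy,
    x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z,
    b = pdb$atom$b, occupancy = pdb$atom$o
  ))
}

#' @rdname read_model
#' @param atoms a data frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `x`, `y`, `z`, `b` (optionally `element`, `occupancy`).
#' @export
atomic_model <- function(atoms) {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z", "b")
  if (!all(need %in% names(atoms)))
    stop("atomic model needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) == 0) stop("atomic model is empty", call. = FALSE)
  if (any(atoms$b < 0)) stop("negative B-factors", call. = FALSE)
  if (!"element" %in% names(atoms))
    atoms$element <- substr(gsub("[0-9]", "", atoms$atom), 1, 1)
  if (!"occupancy" %in% names(atoms)) atoms$occupancy <- 1
  out <- dplyr::arrange(tibble::as_tibble(atoms), .data$chain, .data$resno)
  class(out) <- c("atomic_model", class(out))
  out
}

#' Write an atomic model in PDB format
#'
#' @param model an `atomic_model`.
#' @param path output `.pdb` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(model[, c("x", "y", "z")])),
                   type = "ATOM", resno = model$resno, resid = model$resname,
                   chain = model$chain, elety = model$atom, b = model$b,
                   o = model$occupancy)
  invisible(path)
}

#' Classify five-residue segments by mean B-factor
#'
#' Scans each chain in non-overlapping windows of `window` consecutive
#' modelled residues (a trailing shorter segment is classified on its own
#' mean) and computes the mean atomic B-factor over all atoms in the
#' window. The class encodes how much structural detail the local density
#' supports:
#'
#' * `full_side_chains` --- mean B < `t_full` (side chains modelled);
#' * `poly_ala` --- `t_full` <= mean B <= `t_polyA` (truncate to
#'   poly-alanine); both boundary values inclusive here;
#' * `removed` --- mean B > `t_polyA` (segment left out of the model).
#'
#' @param model an `atomic_model`.
#' @param window residues per segment (default 5).
#' @param t_full full-side-chain threshold, Angstrom squared (default 110).
#' @param t_polyA poly-alanine upper threshold, Angstrom squared
#'   (default 150).
#' @return A tibble of class `segment_report`: chain, segment index,
#'   res_start, res_end, n_res, mean_b, class.
#' @export
segment_bfactor_classify <- function(model, window = 5,
                                     t_full = 110, t_polyA = 150) {
  stopifnot(inherits(model, "atomic_model"), window >= 1, t_full <= t_polyA)
  res <- dplyr::distinct(model, .data$chain, .data$resno)
  segs <- res |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(segment = (dplyr::row_number() - 1) %/% window + 1) |>
    dplyr::ungroup()
  joined <- dplyr::inner_join(model, segs, by = c("chain", "resno"))
  rep <- joined |>
    dplyr::group_by(.data$chain, .data$segment) |>
    dplyr::summarise(res_start = min(.data$resno), res_end = max(.data$resno),
                     n_res = dplyr::n_distinct(.data$resno),
                     mean_b = mean(.data$b), .groups = "drop") |>
    dplyr::mutate(class = dplyr::case_when(
      .data$mean_b < t_full ~ "full_side_chains",
      .data$mean_b <= t_polyA ~ "poly_ala",
      TRUE ~ "removed"
    ))
  class(rep) <- c("segment_report", class(rep))
  attr(rep, "window") <- window
  attr(rep, "thresholds") <- c(t_full = t_full, t_polyA = t_polyA)
  rep
}

#' Apply a segment classification to truncate a model
#'
#' Segments classified `full_side_chains` are kept unchanged; `poly_ala`
#' segments keep only the N, CA, C, O and CB atoms and are renamed to ALA
#' (glycine keeps no CB); `removed` segments are deleted.
#'
#' @param model the `atomic_model` the report was computed from.
#' @param report a `segment_report` from [segment_bfactor_classify()].
#' @return The truncated `atomic_model` (may be empty only in the trivial
#'   all-removed case, in which a zero-row tibble is returned).
#' @export
apply_truncation <- function(model, report) {
  stopifnot(inherits(model, "atomic_model"), inherits(report, "segment_report"))
  window <- attr(report, "window")
  res <- dplyr::distinct(model, .data$chain, .data$resno)
  segs <- res |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(segment = (dplyr::row_number() - 1) %/% window + 1) |>
    dplyr::ungroup()
  m <- model |>
    dplyr::inner_join(segs, by = c("chain", "resno")) |>
    dplyr::inner_join(dplyr::select(report, "chain", "segment", "class"),
                      by = c("chain", "segment"))
  backbone <- c("N", "CA", "C", "O", "CB")
  out <- m |>
    dplyr::filter(.data$class != "removed") |>
    dplyr::filter(.data$class == "full_side_chains" |
                    .data$atom %in% backbone) |>
    dplyr::filter(!(.data$class == "poly_ala" & .data$resname == "GLY" &
                      .data$atom == "CB")) |>
    dplyr::mutate(resname = ifelse(.data$class == "poly_ala", "ALA",
                                   .data$resname)) |>
    dplyr::select(-"segment", -"class")
  if (nrow(out) == 0) {
    class(out) <- c("atomic_model", class(out))
    return(out)
  }
  atomic_model(out)
}

#' Inner angles of a ring hexagon through six labelled C-alpha atoms
#'
#' Connects six atoms (in the given subunit order) into a closed hexagon,
#' projects the vertices onto their least-squares plane (or the plane
#' perpendicular to `axis` when given) and computes the inner angle at
#' each vertex from the adjacent edge vectors. For a convex ring the inner
#' angles sum to 720 degrees; reflex vertices of a concave ring are
#' reported in (180, 360) using the ring's signed area for orientation.
#' Deviations of the angles from 120 degrees quantify the breaking of
#' six-fold symmetry in, e.g., an AAA+ ATPase ring.
#'
#' @param model an `atomic_model`.
#' @param selections a data frame (or list of length-2/3 vectors) with six
#'   rows: columns `chain`, `resno` and optionally `atom` (default `"CA"`),
#'   in ring order.
#' @param axis optional 3-vector: project onto the plane perpendicular to
#'   it instead of the best-fit plane.
#' @return A tibble of class `ring_report`: vertex, chain, resno, x/y/z
#'   (projected), inner_angle (degrees), plus attributes `angle_sum` and
#'   `max_dev_120`.
#' @export
ring_hexagon_angles <- function(model, selections, axis = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  if (is.list(selections) && !is.data.frame(selections))
    selections <- do.call(rbind, lapply(selections, function(s)
      data.frame(chain = s[[1]], resno = as.integer(s[[2]]),
                 atom = if (length(s) > 2) s[[3]] else "CA")))
  if (!"atom" %in% names(selections)) selections$atom <- "CA"
  if (nrow(selections) != 6)
    stop("exactly six selections are required for a hexagon", call. = FALSE)
  pts <- matrix(0, 6, 3)
  for (i in 1:6) {
    hit <- dplyr::filter(model, .data$chain == selections$chain[i],
                         .data$resno == selections$resno[i],
                         .data$atom == selections$atom[i])
    if (nrow(hit) == 0)
      stop(sprintf("atom not found: chain %s resno %d atom %s",
                   selections$chain[i], selections$resno[i],
                   selections$atom[i]), call. = FALSE)
    pts[i, ] <- as.numeric(hit[1, c("x", "y", "z")])
  }
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  normal <- if (!is.null(axis)) axis / sqrt(sum(axis^2)) else {
    sv <- svd(X)
    sv$v[, 3]                               # least-squares plane normal
  }
  # orthonormal in-plane basis
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  uv <- cbind(X %*% e1, X %*% e2)
  # signed area fixes the ring orientation so reflex vertices are detected
  j <- c(2:6, 1)
  area2 <- sum(uv[, 1] * uv[j, 2] - uv[j, 1] * uv[, 2])
  if (abs(area2) < 1e-9)
    stop("degenerate ring geometry: vertices are collinear", call. = FALSE)
  orient <- sign(area2)
  ang <- numeric(6)
  for (i in 1:6) {
    p <- uv[i, ]
    a <- uv[if (i == 1) 6 else i - 1, ] - p
    b <- uv[if (i == 6) 1 else i + 1, ] - p
    raw <- atan2(orient * (b[1] * a[2] - b[2] * a[1]), sum(a * b))
    if (raw < 0) raw <- raw + 2 * pi        # interior angle in (0, 2 pi)
    ang[i] <- raw * 180 / pi
  }
  proj <- sweep(uv %*% rbind(e1, e2), 2, ctr, "+")
  out <- tibble::tibble(vertex = 1:6, chain = selections$chain,
                        resno = selections$resno,
                        x = proj[, 1], y = proj[, 2], z = proj[, 3],
                        inner_angle = ang)
  class(out) <- c("ring_report", class(out))
  attr(out, "angle_sum") <- sum(ang)
  attr(out, "max_dev_120") <- max(abs(ang - 120))
  out
}
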