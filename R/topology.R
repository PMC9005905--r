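#' Create an arterial segment
#'
#' A segment is a tapered compliant tube. Terminal segments carry a
#' three-element Windkessel outflow model; non-terminal segments end in a
#' junction with their children.
#'
#' @param id Integer label (unique within a tree).
#' @param name Human-readable name.
#' @param length_cm Segment length, cm.
#' @param diam_prox_mm,diam_dist_mm Proximal/distal lumen diameter, mm. The
#'   distal diameter must not exceed the proximal one (tapering).
#' @param distensibility Wall distensibility at the reference pressure,
#'   kPa^-1 x 10^-3.
#' @param parent_id Integer id of the parent segment, or `NA` for the root.
#' @param windkessel Terminal load created with [windkessel_outlet()], or
#'   `NULL` for non-terminal segments.
#' @param group Artery group label (e.g. `"aorta"`, `"radial"`); used by the
#'   in-vivo override table and for reporting.
#' @param wall Optional list with elements `p_peak_mmhg`, `p_width_mmhg` and
#'   (optionally) `p_cap_mmhg`: centre and width of the segment's arctangent
#'   compliance-pressure curve, and the pressure above which the wall enters
#'   its linear high-pressure (collagen) regime, used when the
#'   pressure-dependent tube law is active.
#' @return A list of class `artery_segment`.
#' @export
artery_segment <- function(id, name, length_cm, diam_prox_mm, diam_dist_mm,
                           distensibility, parent_id = NA_integer_,
                           windkessel = NULL, group = NULL, wall = NULL) {
  if (!(length_cm > 0)) stop("segment ", id, ": length must be positive")
  if (!(diam_prox_mm > 0) || !(diam_dist_mm > 0))
    stop("segment ", id, ": diameters must be positive")
  if (diam_dist_mm > diam_prox_mm + 1e-9)
    stop("segment ", id, ": distal diameter exceeds proximal (no taper)")
  if (!(distensibility > 0)) stop("segment ", id, ": distensibility must be positive")
  structure(list(id = as.integer(id), name = as.character(name),
                 group = group, length_cm = length_cm,
                 diam_prox_mm = diam_prox_mm, diam_dist_mm = diam_dist_mm,
                 distensibility = distensibility,
                 parent_id = as.integer(parent_id),
                 child_ids = integer(0),
                 windkessel = windkessel, wall = wall),
            class = "artery_segment")
}

#' Three-element Windkessel outflow model
#'
#' Lumped terminal load: proximal (characteristic) resistance `R1` in series
#' with a parallel distal resistance `R2` and compliance `C`, discharging to
#' the venous pressure `P_out`.
#'
#' @param R1,R2 Resistances, mmHg.s/mL.
#' @param C Compliance, mL/mmHg.
#' @param P_out Outflow (venous) pressure, mmHg.
#' @return A list of class `windkessel_outlet`.
#' @export
windkessel_outlet <- function(R1, R2, C, P_out = 5) {
  stopifnot(R1 > 0, R2 > 0, C > 0)
  structure(list(R1 = R1, R2 = R2, C = C, P_out = P_out),
            class = "windkessel_outlet")
}

#' Assemble an arterial tree
#'
#' Builds child links from the segments' `parent_id` fields, attaches named
#' measurement sites, and validates the result.
#'
#' @param segments List of [artery_segment()] objects.
#' @param sites Named list; each element is `list(segment = <id>,
#'   pos_cm = <distance from the proximal end>)`. `pos_cm = NULL` places the
#'   site at the segment midpoint.
#' @param meta Optional metadata list (carried through I/O).
#' @return A list of class `arterial_tree`.
#' @export
arterial_tree <- function(segments, sites = list(), meta = list()) {
  ids <- vapply(segments, function(s) s$id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate segment ids")
  names(segments) <- as.character(ids)
  for (k in names(segments)) segments[[k]]$child_ids <- integer(0)
  for (k in names(segments)) {
    p <- segments[[k]]$parent_id
    if (!is.na(p)) {
      pk <- as.character(p)
      if (is.null(segments[[pk]]))
        stop("segment ", k, " references missing parent ", p)
      segments[[pk]]$child_ids <- c(segments[[pk]]$child_ids, segments[[k]]$id)
    }
  }
  roots <- ids[vapply(segments, function(s) is.na(s$parent_id), logical(1))]
  if (length(roots) != 1) stop("tree must have exactly one root, found ", length(roots))
  for (nm in names(sites)) {
    s <- sites[[nm]]
    seg <- segments[[as.character(s$segment)]]
    if (is.null(seg)) stop("site '", nm, "' references missing segment ", s$segment)
    if (is.null(s$pos_cm)) sites[[nm]]$pos_cm <- seg$length_cm / 2
  }
  tree <- structure(list(segments = segments, root_id = roots[[1]],
                         sites = sites, meta = meta),
                    class = "arterial_tree")
  validate_tree(tree)
  tree
}

#' Validate an arterial tree
#'
#' Checks connectivity, acyclicity, the terminal/Windkessel pairing, and
#' site resolution. Called by all constructors and surgery operations.
#'
#' @param tree An [arterial_tree].
#' @return The tree, invisibly; stops with a structural error otherwise.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "arterial_tree"))
  segs <- tree$segments
  # reachability from root and cycle detection
  seen <- character(0)
  stack <- as.character(tree$root_id)
  while (length(stack)) {
    k <- stack[[1]]; stack <- stack[-1]
    if (k %in% seen) stop("cycle detected at segment ", k)
    seen <- c(seen, k)
    kids <- segs[[k]]$child_ids
    if (length(kids)) {
      for (cid in kids) {
        ck <- as.character(cid)
        if (is.null(segs[[ck]])) stop("dangling child reference ", cid, " in segment ", k)
        if (!identical(segs[[ck]]$parent_id, segs[[k]]$id))
          stop("parent/child mismatch between ", k, " and ", ck)
      }
      stack <- c(stack, as.character(kids))
    }
  }
  if (length(seen) != length(segs))
    stop("tree is not connected: ", length(segs) - length(seen), " unreachable segment(s)")
  for (k in names(segs)) {
    s <- segs[[k]]
    terminal <- length(s$child_ids) == 0
    if (terminal && is.null(s$windkessel))
      stop("terminal segment ", k, " lacks a Windkessel outlet")
    if (!terminal && !is.null(s$windkessel))
      stop("non-terminal segment ", k, " carries a Windkessel outlet")
  }
  for (nm in names(tree$sites)) {
    st <- tree$sites[[nm]]
    seg <- segs[[as.character(st$segment)]]
    if (is.null(seg)) stop("site '", nm, "' references missing segment")
    if (st$pos_cm < 0 || st$pos_cm > seg$length_cm + 1e-9)
      stop("site '", nm, "' lies outside its segment")
  }
  invisible(tree)
}

#' Is a segment terminal?
#' @param tree An [arterial_tree].
#' @param id Segment id.
#' @return Logical.
#' @export
is_terminal <- function(tree, id) {
  seg <- tree$segments[[as.character(id)]]
  if (is.null(seg)) stop("no segment with id ", id)
  length(seg$child_ids) == 0
}

#' Terminal segment ids of a tree
#' @param tree An [arterial_tree].
#' @return Integer vector.
#' @export
terminal_ids <- function(tree) {
  ids <- vapply(tree$segments, function(s) s$id, integer(1))
  unname(ids[vapply(tree$segments, function(s) length(s$child_ids) == 0, logical(1))])
}

#' @export
print.arterial_tree <- function(x, ...) {
  cat("<arterial_tree> ", length(x$segments), " segments, ",
      length(terminal_ids(x)), " terminal, root id ", x$root_id, "\n", sep = "")
  if (length(x$sites))
    cat("sites:", paste(names(x$sites), collapse = ", "), "\n")
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Write an arterial tree to a JSON topology file
#'
#' The schema has a `units` header block, the root id, the named sites and
#' one record per segment. [load_tree()] reads the same schema back;
#' write/read round-trips are lossless.
#'
#' @param tree An [arterial_tree].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_tree <- function(tree, path) {
  validate_tree(tree)
  segs <- unname(lapply(tree$segments, function(s) {
    rec <- list(id = s$id, name = s$name, group = s$group,
                length_cm = s$length_cm, diam_prox_mm = s$diam_prox_mm,
                diam_dist_mm = s$diam_dist_mm, distensibility = s$distensibility)
    if (!is.na(s$parent_id)) rec$parent_id <- s$parent_id
    if (!is.null(s$windkessel)) rec$windkessel <- unclass(s$windkessel)
    if (!is.null(s$wall)) rec$wall <- Filter(Negate(is.null), s$wall)
    rec
  }))
  doc <- list(
    format = "pulsetree-topology",
    units = list(length = "cm", diameter = "mm",
                 distensibility = "kPa^-1 x 10^-3",
                 resistance = "mmHg.s/mL", compliance = "mL/mmHg",
                 pressure = "mmHg"),
    root_id = tree$root_id,
    sites = lapply(tree$sites, function(s) list(segment = s$segment, pos_cm = s$pos_cm)),
    segments = segs,
    meta = tree$meta
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load an arterial tree from a JSON topology file
#'
#' @param path Path to a file written by [save_tree()] (or conforming to the
#'   same schema).
#' @return A validated [arterial_tree].
#' @export
load_tree <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse topology file: ",
                                           conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "pulsetree-topology"))
    stop("parse error: missing or unknown 'format' field")
  req <- c("root_id", "segments")
  for (f in req) if (is.null(doc[[f]])) stop("parse error: missing field '", f, "'")
  segs <- lapply(doc$segments, function(r) {
    for (f in c("id", "name", "length_cm", "diam_prox_mm", "diam_dist_mm",
                "distensibility"))
      if (is.null(r[[f]])) stop("parse error: segment record missing field '", f, "'")
    wk <- if (!is.null(r$windkessel))
      windkessel_outlet(r$windkessel$R1, r$windkessel$R2, r$windkessel$C,
                        r$windkessel$P_out %||% 5)
    pid <- r$parent_id
    if (is.null(pid) || length(pid) == 0) pid <- NA_integer_
    artery_segment(r$id, r$name, r$length_cm, r$diam_prox_mm, r$diam_dist_mm,
                   r$distensibility,
                   parent_id = pid,
                   windkessel = wk, group = r$group,
                   wall = r$wall)
  })
  sites <- lapply(doc$sites %||% list(),
                  function(s) list(segment = as.integer(s$segment), pos_cm = s$pos_cm))
  tree <- arterial_tree(segs, sites, meta = doc$meta %||% list())
  if (!identical(tree$root_id, as.integer(doc$root_id)))
    stop("structural error: declared root_id does not match parent links")
  tree
}

# ---- surgery ----------------------------------------------------------------

#' Remove a terminal segment
#'
#' Deletes a terminal segment together with its Windkessel and updates the
#' parent's child list. Sites on the removed segment are dropped with a
#' warning. Refuses to remove non-terminal segments (that would orphan the
#' downstream subtree) or the last child of a vessel (that would leave an
#' unterminated tube).
#'
#' @param tree An [arterial_tree].
#' @param segment_id Id of the terminal segment to remove.
#' @return The modified tree.
#' @export
remove_segment <- function(tree, segment_id) {
  k <- as.character(segment_id)
  seg <- tree$segments[[k]]
  if (is.null(seg)) stop("no segment with id ", segment_id)
  if (is.na(seg$parent_id)) stop("refusing to remove the root segment")
  if (length(seg$child_ids) > 0)
    stop("refusing to remove non-terminal segment ", segment_id,
         ": would orphan its subtree")
  pk <- as.character(seg$parent_id)
  sibs <- setdiff(tree$segments[[pk]]$child_ids, seg$id)
  if (length(sibs) == 0)
    stop("refusing to remove segment ", segment_id,
         ": parent would be left without outflow")
  tree$segments[[pk]]$child_ids <- sibs
  tree$segments[[k]] <- NULL
  on_removed <- vapply(tree$sites, function(s) s$segment == segment_id, logical(1))
  if (any(on_removed)) {
    warning("dropping site(s) on removed segment: ",
            paste(names(tree$sites)[on_removed], collapse = ", "))
    tree$sites <- tree$sites[!on_removed]
  }
  validate_tree(tree)
  tree
}

#' Transplant a donor branch onto a terminal segment
#'
#' Re-creates surgical attachment of a donor artery (e.g. a renal artery)
#' onto a terminal recipient vessel (e.g. the external iliac artery): the
#' recipient's Windkessel is removed and the recipient becomes a junction
#' feeding (a) a new branch carrying the donor's geometry, wall and
#' Windkessel properties and (b) a short distal continuation stub that
#' inherits the recipient's distal calibre, wall properties and original
#' Windkessel, so that the downstream vascular bed remains perfused.
#'
#' @param tree An [arterial_tree].
#' @param donor_id Id of the donor segment, looked up in `donor_tree` (the
#'   donor may have been removed from `tree` itself, as in a staged-removal
#'   protocol).
#' @param target_id Id of the terminal recipient segment in `tree`.
#' @param donor_tree Tree holding the donor segment's properties; defaults
#'   to `tree`.
#' @param stub_length_cm Length of the distal continuation stub, cm.
#' @return The modified tree.
#' @export
transplant_segment <- function(tree, donor_id, target_id, donor_tree = tree,
                               stub_length_cm = 2) {
  donor <- donor_tree$segments[[as.character(donor_id)]]
  if (is.null(donor)) stop("donor segment ", donor_id, " not found in donor tree")
  if (is.null(donor$windkessel))
    stop("donor segment ", donor_id, " has no Windkessel outlet to carry over")
  tk <- as.character(target_id)
  target <- tree$segments[[tk]]
  if (is.null(target)) stop("no segment with id ", target_id)
  if (length(target$child_ids) > 0)
    stop("transplant target ", target_id, " must be terminal")
  if (!is.null(tree$segments[[as.character(donor_id)]]))
    stop("tree already contains a segment with the donor id ", donor_id)
  graft <- artery_segment(donor$id, paste0(donor$name, "_graft"),
                          donor$length_cm, donor$diam_prox_mm, donor$diam_dist_mm,
                          donor$distensibility, parent_id = target$id,
                          windkessel = donor$windkessel, group = donor$group,
                          wall = donor$wall)
  stub_id <- max(vapply(tree$segments, function(s) s$id, integer(1))) + 1L
  stub <- artery_segment(stub_id, paste0(target$name, "_distal"),
                         stub_length_cm, target$diam_dist_mm, target$diam_dist_mm,
                         target$distensibility, parent_id = target$id,
                         windkessel = target$windkessel, group = target$group,
                         wall = target$wall)
  tree$segments[[tk]]$windkessel <- NULL
  tree$segments[[tk]]$child_ids <- c(graft$id, stub_id)
  tree$segments[[as.character(graft$id)]] <- graft
  tree$segments[[as.character(stub_id)]] <- stub
  validate_tree(tree)
  tree
}

#' Kidney configuration descriptor
#'
#' The four staged-renal-removal configurations: `2KDN` (control, both
#' kidneys), `1KDN` (left renal artery removed), `0KDN` (both renal arteries
#' removed), and `TX` (both removed, right renal artery grafted onto the
#' external iliac artery).
#'
#' @param name One of `"2KDN"`, `"1KDN"`, `"0KDN"`, `"TX"`.
#' @param left_renal,right_renal,iliac_target Segment ids of the left renal
#'   artery, right renal artery and the transplant recipient (external
#'   iliac); defaults follow the reference tree numbering.
#' @return A list of class `kidney_configuration`.
#' @export
kidney_configuration <- function(name, left_renal = 36L, right_renal = 38L,
                                 iliac_target = 44L) {
  name <- match.arg(name, c("2KDN", "1KDN", "0KDN", "TX"))
  removed <- switch(name,
                    "2KDN" = integer(0),
                    "1KDN" = left_renal,
                    "0KDN" = c(left_renal, right_renal),
                    "TX"   = c(left_renal, right_renal))
  transplant <- if (name == "TX") c(donor = right_renal, target = iliac_target)
  structure(list(name = name, removed_segment_ids = as.integer(removed),
                 transplant = transplant),
            class = "kidney_configuration")
}

#' Apply a kidney configuration to the reference tree
#'
#' Composes [remove_segment()] and [transplant_segment()] according to the
#' configuration descriptor. `2KDN` returns the tree unchanged.
#'
#' @param tree The two-kidney reference [arterial_tree].
#' @param config A [kidney_configuration()] or its name.
#' @return The configured tree.
#' @export
apply_kidney_configuration <- function(tree, config) {
  if (is.character(config)) config <- kidney_configuration(config)
  stopifnot(inherits(config, "kidney_configuration"))
  original <- tree
  for (id in config$removed_segment_ids) tree <- remove_segment(tree, id)
  if (!is.null(config$transplant))
    tree <- transplant_segment(tree, config$transplant[["donor"]],
                               config$transplant[["target"]],
                               donor_tree = original)
  tree$meta$kidney_configuration <- config$name
  tree
}

# ---- path measurement -------------------------------------------------------

ancestor_chain <- function(tree, id) {
  chain <- integer(0)
  k <- id
  while (!is.na(k)) {
    chain <- c(chain, k)
    k <- tree$segments[[as.character(k)]]$parent_id
  }
  chain
}

#' Distance between two named arterial sites
#'
#' Measures the anatomical path between two sites through the tree (via
#' their nearest common ancestor), summing the traversed segment lengths.
#' Junctions sit at the distal end of the parent, so a site's distance to
#' its own segment's proximal junction equals its `pos_cm`.
#'
#' @param tree An [arterial_tree].
#' @param site_a,site_b Site names present in `tree$sites`.
#' @return A list of class `path_measurement` with elements `site_a`,
#'   `site_b`, `segment_chain` (ordered ids from a to b) and `distance_cm`.
#' @export
arterial_path <- function(tree, site_a, site_b) {
  for (nm in c(site_a, site_b))
    if (is.null(tree$sites[[nm]])) stop("unknown site name '", nm, "'")
  sa <- tree$sites[[site_a]]; sb <- tree$sites[[site_b]]
  ca <- ancestor_chain(tree, sa$segment)
  cb <- ancestor_chain(tree, sb$segment)
  lca <- intersect(ca, cb)[1]
  len <- function(id) tree$segments[[as.character(id)]]$length_cm
  up_a <- ca[seq_len(which(ca == lca) - 1)]   # a-side chain below the LCA
  up_b <- cb[seq_len(which(cb == lca) - 1)]
  if (sa$segment == sb$segment) {
    dist <- abs(sa$pos_cm - sb$pos_cm)
    chain <- sa$segment
  } else if (length(up_a) == 0) {
    # site a's segment is the LCA: walk down to b
    between <- setdiff(up_b, sb$segment)
    dist <- (len(sa$segment) - sa$pos_cm) + sum(vapply(between, len, numeric(1))) +
      sb$pos_cm
    chain <- c(sa$segment, rev(between), sb$segment)
  } else if (length(up_b) == 0) {
    between <- setdiff(up_a, sa$segment)
    dist <- (len(sb$segment) - sb$pos_cm) + sum(vapply(between, len, numeric(1))) +
      sa$pos_cm
    chain <- c(sa$segment, between, sb$segment)
  } else {
    # both descend from the junction at the LCA's distal end
    mid_a <- setdiff(up_a, sa$segment)
    mid_b <- setdiff(up_b, sb$segment)
    dist <- sa$pos_cm + sum(vapply(mid_a, len, numeric(1))) +
      sb$pos_cm + sum(vapply(mid_b, len, numeric(1)))
    chain <- c(sa$segment, mid_a, rev(mid_b), sb$segment)
  }
  structure(list(site_a = site_a, site_b = site_b,
                 segment_chain = as.integer(chain), distance_cm = dist),
            class = "path_measurement")
}

#' @export
print.path_measurement <- function(x, ...) {
  cat("<path> ", x$site_a, " -> ", x$site_b, ": ", x$distance_cm, " cm via ",
      paste(x$segment_chain, collapse = ","), "\n", sep = "")
  invisible(x)
}
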