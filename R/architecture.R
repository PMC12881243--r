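#' @useDynLib hebbnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom
NULL

GRID_N <- 25L
N_EXC  <- 625L

#' The twelve-area architecture
#'
#' Area names, functional-system membership and hierarchical role of the
#' twelve modelled cortical areas.  Two systems are language-proximal
#' (perisylvian): auditory (A1, AB, PB) and articulatory (PFi, PMi, M1i);
#' two provide semantic grounding (extrasylvian): visual (V1, TO, AT) and
#' dorsolateral motor (PFL, PML, M1L).  PB, PFi, AT and PFL are multimodal
#' connector hubs.
#'
#' @return A data frame with columns `area`, `system`, `role`
#'   (primary/secondary/hub).
#' @export
area_table <- function() {
  data.frame(
    area   = c("A1", "AB", "PB", "PFi", "PMi", "M1i",
               "V1", "TO", "AT", "PFL", "PML", "M1L"),
    system = rep(c("auditory", "articulatory", "visual", "dorsolateral"),
                 each = 3),
    role   = c("primary", "secondary", "hub", "hub", "secondary", "primary",
               "primary", "secondary", "hub", "hub", "secondary", "primary"),
    stringsAsFactors = FALSE)
}

#' Default inter-area link table
#'
#' Reciprocal excitatory links between areas, encoded once per undirected
#' pair.  Within each system the three areas form a next-neighbour chain
#' plus a jumping link between its primary and hub area.  Cross-system
#' links comprise jumping links between adjacent systems' secondary and hub
#' areas (AB-PFi, PB-PMi within the perisylvian pair; TO-PFL, AT-PML within
#' the extrasylvian pair) and long-distance links among all six pairs of
#' connector hubs (PB, PFi, AT, PFL).  Within-system links use the stronger
#' between-area kernel amplitude, cross-system links the halved one.  The
#' table is plain data and can be edited before network construction.
#'
#' @return Data frame with columns `a`, `b`, `class`
#'   (`within_system`/`cross_system`).
#' @export
default_link_table <- function() {
  within <- rbind(
    c("A1", "AB"), c("AB", "PB"), c("A1", "PB"),
    c("PFi", "PMi"), c("PMi", "M1i"), c("PFi", "M1i"),
    c("V1", "TO"), c("TO", "AT"), c("V1", "AT"),
    c("PFL", "PML"), c("PML", "M1L"), c("PFL", "M1L"))
  cross <- rbind(
    c("AB", "PFi"), c("PB", "PMi"),    # adjacent perisylvian systems
    c("TO", "PFL"), c("AT", "PML"),    # adjacent extrasylvian systems
    c("PB", "PFi"), c("PB", "AT"), c("PB", "PFL"),
    c("PFi", "AT"), c("PFi", "PFL"), c("AT", "PFL"))  # hub-hub
  data.frame(
    a = c(within[, 1], cross[, 1]),
    b = c(within[, 2], cross[, 2]),
    class = rep(c("within_system", "cross_system"),
                c(nrow(within), nrow(cross))),
    stringsAsFactors = FALSE)
}

#' Construct an architecture description
#'
#' @param areas Data frame as returned by [area_table()].
#' @param links Link table as returned by [default_link_table()].
#' @param grid_n Grid side length (cells).
#' @return An object of class `architecture`.
#' @export
architecture <- function(areas = area_table(), links = default_link_table(),
                         grid_n = GRID_N) {
  bad <- setdiff(c(links$a, links$b), areas$area)
  if (length(bad))
    stop("architecture: link table references unknown areas: ",
         paste(bad, collapse = ", "))
  structure(list(areas = areas, links = links, grid_n = grid_n,
                 n_exc = grid_n^2),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat("architecture:", nrow(x$areas), "areas on", x$grid_n, "x", x$grid_n,
      "toroidal grids;", nrow(x$links), "reciprocal inter-area links\n")
  invisible(x)
}

#' Projection specification
#'
#' Describes one set of synapses between two grids: its synapse class, the
#' wiring rule (a Gaussian kernel or a deterministic scheme), the class
#' strength multiplier, its delay in excitatory-step units, and whether it
#' is plastic.  Only excitatory-to-excitatory projections are plastic.
#'
#' @param source_area,target_area Area names.
#' @param synapse_class One of `"EE_local"`, `"EE_between"`, `"EI"`,
#'   `"IE"`, `"E_GI"`, `"GI_E"`.
#' @param kernel Optional [kernel_spec()] override; the class default is
#'   used when `NULL`.
#' @param exclude_self For `EE_local`: exclude autapses (default `TRUE`).
#' @param w_up Upper bound of the uniform weight initialisation for
#'   excitatory-to-excitatory synapses.
#' @return An object of class `projection_spec`.
#' @export
projection_spec <- function(source_area, target_area, synapse_class,
                            kernel = NULL, exclude_self = TRUE,
                            w_up = 0.1) {
  defaults <- list(
    EE_local   = list(kernel = kernel_spec(3.2,  k_c = 0.15,  half_width = 9),
                      strength = 500, delay = 1,   plastic = TRUE),
    EE_between = list(kernel = kernel_spec(9,    k_c = 0.13,  half_width = 9),
                      strength = 500, delay = 1,   plastic = TRUE),
    EI         = list(kernel = kernel_spec(1.42, k_c = 0.295, half_width = 2),
                      strength = 1,   delay = 0.5, plastic = FALSE),
    IE         = list(kernel = NULL, strength = 1500, delay = 0.5,
                      plastic = FALSE),
    E_GI       = list(kernel = NULL, strength = 1,    delay = 0.5,
                      plastic = FALSE),
    GI_E       = list(kernel = NULL, strength = 65,   delay = 0.5,
                      plastic = FALSE))
  if (!synapse_class %in% names(defaults))
    stop("projection_spec: unknown synapse_class '", synapse_class, "'")
  d <- defaults[[synapse_class]]
  if (!is.null(kernel)) d$kernel <- kernel
  structure(
    list(source_area = source_area, target_area = target_area,
         synapse_class = synapse_class, kernel = d$kernel,
         strength = d$strength, delay = d$delay, plastic = d$plastic,
         exclude_self = isTRUE(exclude_self) && synapse_class == "EE_local",
         w_up = w_up),
    class = "projection_spec")
}

#' Wire one projection by pairwise Bernoulli trials
#'
#' For kernel-based excitatory-to-excitatory classes, every source-target
#' pair whose toroidal offset lies inside the kernel window is an
#' independent Bernoulli trial at the kernel probability; formed synapses
#' draw their initial weight uniformly from `[0, w_up]`.
#' Excitatory-to-inhibitory projections connect each source to its full
#' 5x5 neighbourhood with probability 1 and weight equal to the kernel
#' value at the offset.  Inhibitory-to-excitatory projections are
#' one-to-one at identical grid coordinates; global-inhibition projections
#' are all-to-one and one-to-all.  Deterministic classes carry weight 1.
#'
#' @param spec A [projection_spec()].
#' @param seed Integer seed; identical seeds give identical edge lists.
#' @return An object of class `projection`: the spec plus an edge table
#'   with 0-based `pre`, `post` indices and `weight`.
#' @export
wire_projection <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "projection_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- GRID_N
  ne <- N_EXC
  cls <- spec$synapse_class
  if (cls %in% c("EE_local", "EE_between")) {
    kern <- spec$kernel
    hw <- kern$half_width
    src <- 0:(ne - 1L)
    rc <- grid_coords(src, n)
    pres <- posts <- vector("list", (2L * hw + 1L)^2)
    m <- 0L
    for (dx in -hw:hw) {
      for (dy in -hw:hw) {
        if (cls == "EE_local" && spec$exclude_self && dx == 0L && dy == 0L)
          next
        p <- kernel_probability(kern, dx, dy)
        if (p <= 0) next
        hit <- stats::rbinom(ne, 1L, p) == 1L
        if (!any(hit)) next
        m <- m + 1L
        pres[[m]] <- src[hit]
        posts[[m]] <- grid_index(rc[hit, "row"] + dx, rc[hit, "col"] + dy, n)
      }
    }
    pre <- unlist(pres[seq_len(m)], use.names = FALSE)
    post <- unlist(posts[seq_len(m)], use.names = FALSE)
    weight <- stats::runif(length(pre), 0, spec$w_up)
  } else if (cls == "EI") {
    kern <- spec$kernel
    hw <- kern$half_width
    off <- expand.grid(dx = -hw:hw, dy = -hw:hw)
    src <- rep(0:(ne - 1L), each = nrow(off))
    dx <- rep(off$dx, times = ne)
    dy <- rep(off$dy, times = ne)
    rc <- grid_coords(src, n)
    pre <- src
    post <- grid_index(rc[, "row"] + dx, rc[, "col"] + dy, n)
    weight <- kernel_probability(kern, dx, dy)
  } else if (cls == "IE") {
    pre <- post <- 0:(ne - 1L)
    weight <- rep(1, ne)
  } else if (cls == "E_GI") {
    pre <- 0:(ne - 1L)
    post <- rep(0L, ne)
    weight <- rep(1, ne)
  } else if (cls == "GI_E") {
    pre <- rep(0L, ne)
    post <- 0:(ne - 1L)
    weight <- rep(1, ne)
  } else {
    stop("wire_projection: unknown synapse_class '", cls, "'")
  }
  structure(list(spec = spec,
                 edges = data.frame(pre = as.integer(pre),
                                    post = as.integer(post),
                                    weight = weight)),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat("projection", x$spec$source_area, "->", x$spec$target_area,
      sprintf("[%s]", x$spec$synapse_class), nrow(x$edges), "edges\n")
  invisible(x)
}

#' Empirical mean out-degree of a wired projection
#'
#' @param projection A [wire_projection()] result.
#' @param n_source Number of source units (default 625).
#' @return Mean number of outgoing edges per source unit.
#' @export
mean_out_degree <- function(projection, n_source = N_EXC) {
  nrow(projection$edges) / n_source
}

#' Build the full twelve-area wiring
#'
#' Instantiates, for every area, the five local projection classes
#' (excitatory-to-excitatory, excitatory-to-inhibitory,
#' inhibitory-to-excitatory, and the two global-inhibition classes), and
#' for every entry of the link table a reciprocal pair of between-area
#' excitatory projections with kernel amplitude 0.13 (within system) or
#' 0.065 (cross system) at sigma 9.  Per-projection seeds are derived
#' deterministically from the master seed so the architecture is
#' reproducible piecewise.
#'
#' @param arch An [architecture()]; defaults to the standard twelve areas.
#' @param seed Master integer seed.
#' @param exclude_self Exclude autapses in local excitatory wiring.
#' @return List with elements `architecture` and `projections` (a named
#'   list of `projection` objects).
#' @export
build_architecture <- function(arch = architecture(), seed = 1L,
                               exclude_self = TRUE) {
  stopifnot(inherits(arch, "architecture"))
  areas <- arch$areas$area
  local_classes <- c("EE_local", "EI", "IE", "E_GI", "GI_E")
  n_proj <- length(areas) * length(local_classes) + 2L * nrow(arch$links)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_proj)
  projections <- vector("list", n_proj)
  nms <- character(n_proj)
  k <- 0L
  for (a in areas) {
    for (cls in local_classes) {
      k <- k + 1L
      projections[[k]] <- wire_projection(
        projection_spec(a, a, cls, exclude_self = exclude_self),
        seed = child_seeds[k])
      nms[k] <- paste(a, a, cls, sep = ".")
    }
  }
  cross_kernel <- kernel_spec(9, k_c = 0.065, half_width = 9)
  for (i in seq_len(nrow(arch$links))) {
    pair <- c(arch$links$a[i], arch$links$b[i])
    kern <- if (arch$links$class[i] == "cross_system") cross_kernel else NULL
    for (dir in 1:2) {
      k <- k + 1L
      s <- pair[dir]; t <- pair[3L - dir]
      projections[[k]] <- wire_projection(
        projection_spec(s, t, "EE_between", kernel = kern),
        seed = child_seeds[k])
      nms[k] <- paste(s, t, "EE_between", sep = ".")
    }
  }
  names(projections) <- nms
  list(architecture = arch, projections = projections)
}
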