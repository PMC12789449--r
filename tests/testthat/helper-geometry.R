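# shared fixtures: all geometry is generated in code, nothing on disk

# a random rigid transform with bounded rotation angle / translation
random_rigid <- function(max_angle = 180, max_trans = 20) {
  axis <- rnorm(3)
  rigid_transform(
    rotation_about_axis(axis, runif(1, -max_angle, max_angle)),
    runif(3, -max_trans, max_trans))
}

# a random implant pose anywhere in a desk-scale volume
random_pose <- function(spec = implant_spec()) {
  coronal <- runif(3, -30, 30)
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  implant_pose(coronal, coronal + spec$length * axis)
}

# max distance between corresponding vertices after applying two transforms
transform_discrepancy <- function(t1, t2, points) {
  max(sqrt(rowSums((transform_points(t1, points) -
                      transform_points(t2, points))^2)))
}

# a crude icosahedron-based sphere mesh (isotropic: no preferred axis)
sphere_mesh <- function(radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2)) * radius
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  tri_mesh(v, f)
}
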