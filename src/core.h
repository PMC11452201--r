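#ifndef FIBROMORPH_CORE_H
#define FIBROMORPH_CORE_H

#include <Rcpp.h>
#include <vector>

// Squared Euclidean distance from every voxel to the nearest voxel of `set`,
// on a grid of dim (nz, ny, nx) stored column-major (index = z + nz*(y + ny*x))
// with physical spacing (sz, sy, sx). If border_in_set, the virtual voxel
// layer just outside each face counts as part of the set.
void dist_to_set_sq(const int* set, const int nz, const int ny, const int nx,
                    const double sz, const double sy, const double sx,
                    const bool border_in_set, std::vector<double>& d2);

#endif
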