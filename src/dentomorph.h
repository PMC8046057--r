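#ifndef DENTOMORPH_H
#define DENTOMORPH_H

#include <Rcpp.h>
#include <vector>

// Squared Euclidean distance from every voxel to the nearest feature voxel.
// If outside_feature, lattice points outside the volume count as features
// (distance 1 from a face voxel).
void sqedt_internal(const std::vector<char>& feature,
                    int nx, int ny, int nz,
                    bool outside_feature,
                    std::vector<double>& out);

#endif
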