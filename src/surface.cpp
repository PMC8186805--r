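// Scalp surface extraction from a voxel label grid.
//
// Surface elements are the centres of voxel faces separating a non-air
// voxel from air (or from outside the grid).  Adjacency links any two
// face centres closer than a cutoff radius (default 2.3 voxel lengths),
// which on a planar patch yields the 16-neighbourhood (axis, diagonal
// and knight moves) whose shortest-path metric approximates Euclidean
// geodesics to within about 2%.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// [[Rcpp::export(name = ".surface_faces")]]
List surface_faces(IntegerVector labels, IntegerVector dims, double h,
                   NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int steps[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  std::vector<double> cx, cy, cz, nxv, nyv, nzv;
  std::vector<int> vox;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t idx = static_cast<R_xlen_t>(i) + nx * (static_cast<R_xlen_t>(j) + static_cast<R_xlen_t>(ny) * k);
        if (labels[idx] == 0) continue;
        for (int f = 0; f < 6; ++f) {
          int ni = i + steps[f][0], nj = j + steps[f][1], nk = k + steps[f][2];
          bool air;
          if (ni < 0 || ni >= nx || nj < 0 || nj >= ny || nk < 0 || nk >= nz) air = true;
          else {
            R_xlen_t nidx = static_cast<R_xlen_t>(ni) + nx * (static_cast<R_xlen_t>(nj) + static_cast<R_xlen_t>(ny) * nk);
            air = (labels[nidx] == 0);
          }
          if (!air) continue;
          cx.push_back(origin[0] + (i + 0.5) * h + 0.5 * h * steps[f][0]);
          cy.push_back(origin[1] + (j + 0.5) * h + 0.5 * h * steps[f][1]);
          cz.push_back(origin[2] + (k + 0.5) * h + 0.5 * h * steps[f][2]);
          nxv.push_back(steps[f][0]); nyv.push_back(steps[f][1]); nzv.push_back(steps[f][2]);
          vox.push_back(static_cast<int>(idx) + 1);  // 1-based voxel index
        }
      }
  R_xlen_t n = cx.size();
  NumericMatrix pts(n, 3), nrm(n, 3);
  IntegerVector voxel(n);
  for (R_xlen_t q = 0; q < n; ++q) {
    pts(q,0)=cx[q]; pts(q,1)=cy[q]; pts(q,2)=cz[q];
    nrm(q,0)=nxv[q]; nrm(q,1)=nyv[q]; nrm(q,2)=nzv[q];
    voxel[q]=vox[q];
  }
  return List::create(_["points"] = pts, _["normals"] = nrm, _["voxel"] = voxel);
}

// [[Rcpp::export(name = ".surface_edges")]]
List surface_edges(NumericMatrix pts, double h, double cutoff_factor) {
  const R_xlen_t n = pts.nrow();
  const double cutoff = cutoff_factor * h;
  const double cut2 = cutoff * cutoff;
  const double cell = h;
  std::unordered_map<long long, std::vector<int> > hashmap;
  hashmap.reserve(n * 2);
  auto key = [cell](double x, double y, double z) -> long long {
    long long ix = static_cast<long long>(std::floor(x / cell));
    long long iy = static_cast<long long>(std::floor(y / cell));
    long long iz = static_cast<long long>(std::floor(z / cell));
    return ((ix + 1048576LL) << 42) ^ ((iy + 1048576LL) << 21) ^ (iz + 1048576LL);
  };
  for (R_xlen_t q = 0; q < n; ++q)
    hashmap[key(pts(q,0), pts(q,1), pts(q,2))].push_back(static_cast<int>(q));

  int reach = static_cast<int>(std::ceil(cutoff / cell)) + 1;
  std::vector<int> ea, eb; std::vector<double> ew;
  for (R_xlen_t q = 0; q < n; ++q) {
    double x = pts(q,0), y = pts(q,1), z = pts(q,2);
    long long ix = static_cast<long long>(std::floor(x / cell));
    long long iy = static_cast<long long>(std::floor(y / cell));
    long long iz = static_cast<long long>(std::floor(z / cell));
    for (long long dx = -reach; dx <= reach; ++dx)
      for (long long dy = -reach; dy <= reach; ++dy)
        for (long long dz = -reach; dz <= reach; ++dz) {
          long long kk = (((ix+dx) + 1048576LL) << 42) ^ (((iy+dy) + 1048576LL) << 21) ^ ((iz+dz) + 1048576LL);
          auto it = hashmap.find(kk);
          if (it == hashmap.end()) continue;
          for (int r : it->second) {
            if (r <= q) continue;
            double ddx = pts(r,0)-x, ddy = pts(r,1)-y, ddz = pts(r,2)-z;
            double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
            if (d2 > 1e-12 && d2 <= cut2) {
              ea.push_back(static_cast<int>(q) + 1);
              eb.push_back(r + 1);
              ew.push_back(std::sqrt(d2));
            }
          }
        }
  }
  return List::create(_["from"] = wrap(ea), _["to"] = wrap(eb), _["weight"] = wrap(ew));
}
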