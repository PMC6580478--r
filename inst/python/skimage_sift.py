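"""Reference SIFT extractor (scikit-image backend).

Reads a whitespace-delimited intensity matrix, runs skimage.feature.SIFT with
parameters passed on the command line, and writes one CSV row per keypoint:
row,col,scale,orientation_deg,d1..d128 (descriptors L2-normalized).
"""
import sys

import numpy as np
from skimage.feature import SIFT


def main():
    in_txt, out_csv = sys.argv[1], sys.argv[2]
    n_octaves, n_scales = int(sys.argv[3]), int(sys.argv[4])
    sigma_min, c_dog, c_edge = float(sys.argv[5]), float(sys.argv[6]), float(sys.argv[7])

    img = np.loadtxt(in_txt).astype(np.float32)
    sift = SIFT(upsampling=1, n_octaves=n_octaves, n_scales=n_scales,
                sigma_min=sigma_min, sigma_in=0.5, c_dog=c_dog, c_edge=c_edge)
    try:
        sift.detect_and_extract(img)
        pos = sift.positions.astype(np.float64)
        sig = sift.sigmas.astype(np.float64)[:, None]
        ori = (np.degrees(sift.orientations.astype(np.float64)) % 360.0)[:, None]
        desc = sift.descriptors.astype(np.float64)
        norms = np.linalg.norm(desc, axis=1, keepdims=True)
        norms[norms == 0] = 1.0
        desc = desc / norms
        out = np.hstack([pos, sig, ori, desc])
    except RuntimeError:
        out = np.zeros((0, 132))
    np.savetxt(out_csv, out, delimiter=",")


if __name__ == "__main__":
    main()
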