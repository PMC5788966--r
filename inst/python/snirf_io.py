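"""HDF5 layer for SNIRF read/write.

Called by the R package with a JSON job description on argv[1]:
  {"mode": "write", "path": ..., "payload": <csv dir>} or
  {"mode": "read"|"check", "path": ...}
Numeric payload travels as flat CSV files in a scratch directory to avoid
JSON float round-off; this script only moves arrays in and out of HDF5.
"""
import json
import os
import sys

import h5py
import numpy as np


def _write_str(grp, name, value):
    grp.create_dataset(name, data=np.bytes_(value))


def write_snirf(path, payload_dir):
    meta = json.load(open(os.path.join(payload_dir, "meta.json")))
    with h5py.File(path, "w") as f:
        _write_str(f, "formatVersion", "1.0")
        nirs = f.create_group("/nirs")
        md = nirs.create_group("metaDataTags")
        _write_str(md, "SubjectID", meta.get("subject_id", "sim"))
        _write_str(md, "MeasurementDate", "2000-01-01")
        _write_str(md, "MeasurementTime", "00:00:00")
        _write_str(md, "LengthUnit", "cm")
        _write_str(md, "TimeUnit", "s")
        _write_str(md, "FrequencyUnit", "Hz")

        probe = nirs.create_group("probe")
        probe.create_dataset("wavelengths", data=np.asarray(meta["wavelengths"], float))
        pos = np.asarray(meta["source_pos"], float).reshape(-1, 3)
        probe.create_dataset("sourcePos3D", data=pos)
        dpos = np.asarray(meta["detector_pos"], float).reshape(-1, 3)
        probe.create_dataset("detectorPos3D", data=dpos)

        ml = np.loadtxt(os.path.join(payload_dir, "measlist.csv"),
                        delimiter=",", skiprows=1, ndmin=2)
        fs = float(meta["sfreq"])
        n_landings = int(meta["n_landings"])
        t0 = 0.0
        for i in range(n_landings):
            d = np.loadtxt(os.path.join(payload_dir, f"landing{i + 1}.csv"),
                           delimiter=",", ndmin=2)
            blk = nirs.create_group(f"data{i + 1}")
            blk.create_dataset("dataTimeSeries", data=d)
            n = d.shape[0]
            blk.create_dataset("time", data=t0 + np.arange(n) / fs)
            for j in range(ml.shape[0]):
                m = blk.create_group(f"measurementList{j + 1}")
                m.create_dataset("sourceIndex", data=int(ml[j, 0]))
                m.create_dataset("detectorIndex", data=int(ml[j, 1]))
                m.create_dataset("wavelengthIndex", data=int(ml[j, 2]))
                m.create_dataset("dataType", data=1)
                m.create_dataset("dataTypeIndex", data=1)
            stim = nirs.create_group(f"stim{i + 1}")
            _write_str(stim, "name", meta["conditions"][i])
            stim.create_dataset(
                "data", data=np.asarray([[t0, n / fs, 1.0]], float)
            )
            t0 += n / fs


def read_snirf(path, out_dir):
    with h5py.File(path, "r") as f:
        nirs = f["/nirs"]
        meta = {
            "wavelengths": [float(w) for w in nirs["probe/wavelengths"][()]],
            "conditions": [],
            "n_landings": 0,
        }
        blocks = sorted(
            (k for k in nirs.keys() if k.startswith("data")),
            key=lambda k: int(k[4:]),
        )
        meta["n_landings"] = len(blocks)
        for i, k in enumerate(blocks):
            blk = nirs[k]
            d = np.asarray(blk["dataTimeSeries"])
            np.savetxt(os.path.join(out_dir, f"landing{i + 1}.csv"), d,
                       delimiter=",")
            if i == 0:
                t = np.asarray(blk["time"])
                meta["sfreq"] = float(1.0 / np.median(np.diff(t)))
                ml = []
                mkeys = sorted(
                    (m for m in blk.keys() if m.startswith("measurementList")),
                    key=lambda m: int(m[len("measurementList"):]),
                )
                for m in mkeys:
                    g = blk[m]
                    ml.append([
                        int(g["sourceIndex"][()]),
                        int(g["detectorIndex"][()]),
                        int(g["wavelengthIndex"][()]),
                    ])
                np.savetxt(os.path.join(out_dir, "measlist.csv"),
                           np.asarray(ml, int), delimiter=",", fmt="%d",
                           header="source,detector,wavelength")
            sk = f"stim{i + 1}"
            if sk in nirs:
                name = nirs[sk]["name"][()]
                if isinstance(name, bytes):
                    name = name.decode()
                meta["conditions"].append(str(name))
        json.dump(meta, open(os.path.join(out_dir, "meta.json"), "w"))


REQUIRED = [
    "formatVersion",
    "/nirs/metaDataTags/SubjectID",
    "/nirs/metaDataTags/LengthUnit",
    "/nirs/metaDataTags/TimeUnit",
    "/nirs/probe/wavelengths",
    "/nirs/data1/dataTimeSeries",
    "/nirs/data1/time",
    "/nirs/data1/measurementList1/sourceIndex",
    "/nirs/data1/measurementList1/detectorIndex",
    "/nirs/data1/measurementList1/wavelengthIndex",
]


def check_snirf(path):
    issues = []
    with h5py.File(path, "r") as f:
        for req in REQUIRED:
            if req not in f:
                issues.append(f"missing required entry: {req}")
    return issues


def main():
    job = json.loads(sys.argv[1])
    if job["mode"] == "write":
        write_snirf(job["path"], job["payload"])
    elif job["mode"] == "read":
        read_snirf(job["path"], job["payload"])
    elif job["mode"] == "check":
        issues = check_snirf(job["path"])
        print(json.dumps(issues))
    else:
        raise SystemExit(f"unknown mode {job['mode']}")


if __name__ == "__main__":
    main()
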