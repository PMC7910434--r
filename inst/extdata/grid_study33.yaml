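name: study33
points:
  - {eccentricity: 0, angle: 0}
  - {eccentricity: 1, angle: 0}
  - {eccentricity: 1, angle: 45}
  - {eccentricity: 1, angle: 90}
  - {eccentricity: 1, angle: 135}
  - {eccentricity: 1, angle: 180}
  - {eccentricity: 1, angle: 225}
  - {eccentricity: 1, angle: 270}
  - {eccentricity: 1, angle: 315}
  - {eccentricity: 3, angle: 0}
  - {eccentricity: 3, angle: 45}
  - {eccentricity: 3, angle: 90}
  - {eccentricity: 3, angle: 135}
  - {eccentricity: 3, angle: 180}
  - {eccentricity: 3, angle: 225}
  - {eccentricity: 3, angle: 270}
  - {eccentricity: 3, angle: 315}
  - {eccentricity: 5, angle: 0}
  - {eccentricity: 5, angle: 45}
  - {eccentricity: 5, angle: 90}
  - {eccentricity: 5, angle: 135}
  - {eccentricity: 5, angle: 180}
  - {eccentricity: 5, angle: 225}
  - {eccentricity: 5, angle: 270}
  - {eccentricity: 5, angle: 315}
  - {eccentricity: 7, angle: 0}
  - {eccentricity: 7, angle: 45}
  - {eccentricity: 7, angle: 90}
  - {eccentricity: 7, angle: 135}
  - {eccentricity: 7, angle: 180}
  - {eccentricity: 7, angle: 225}
  - {eccentricity: 7, angle: 270}
  - {eccentricity: 7, angle: 315}
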