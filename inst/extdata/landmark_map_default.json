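{
  "_comment": "Default 53-landmark map outlining the analysed facial regions (eyebrows, eye contours, nose tip, inner eye corners, mouth corners, mid lips). Indices are face-mesh-estimator flavoured but APPROXIMATE: no authoritative index list exists for the region outlines, so edit this file to match your estimator's canonical mesh. Left/right is from the observer's point of view. Eyebrow ids are ordered inner-to-outer; eye contours are ordered closed polygons that include the inner eye corner.",
  "left_eyebrow": [55, 65, 52, 53, 46],
  "right_eyebrow": [285, 295, 282, 283, 276],
  "left_eye_contour": [133, 155, 154, 153, 145, 144, 163, 7, 33, 246, 161, 160, 159, 158, 157, 173, 130, 25, 110],
  "right_eye_contour": [362, 341, 256, 252, 253, 254, 339, 255, 263, 249, 350, 349, 348, 347, 346, 340, 345, 352, 357],
  "nose_tip": [1],
  "left_inner_eye_corner": [133],
  "right_inner_eye_corner": [362],
  "left_mouth_corner": [61],
  "right_mouth_corner": [291],
  "upper_mid_lip": [0],
  "lower_mid_lip": [17]
}
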