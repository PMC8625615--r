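"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,23.73,24.09,25.31,30.11,33.02,37.29,43.15,50.8,54.52,63.97,67.65,73.73,78.46,85.51,86.87,87.9,89.01,28.7,34.28,37.8,43.36,46.37,65.62,69.55,75.39,79.36,85.66,56.88,56.27,57.79,56.01,49.52,51.34,56.55,60.61,65.55,45.95,42.02,35.42,32.32,32.58,42.02,81.04,78,69.49,68.64,71.42,79.13,72.08,69.39,64.58,56.16,47.45,41.75,41.2,40.89,49.83,56.77,65.64,66.04,65.66,62.37,56.66,47.82,46.75,51.18,55.3,60.84,51.3,59.91,69.29,76.91,79.13,83.93,89.31,92.98,92.34,91.78,89.72,85.44,80.32,72.99,69.08,61.1,52.43,34.69,32.24,32.27,31.68,32.34,33.17,31.71,30.09,33.01,32.47,40.23,45.65,50.3,55.44,58.96,62.6,60.73,60.96,59.32,40.12,40.86,38.63,42.45,44.08,42.65,41.24,38.33,36.96,40.39,43.77,44.31,76.3,72.37,69.69,69.09,68.15,72.48,78.7,78.89,82.12,84.74,84.19,79.35,75.61,71.8,71.76,72,76.02,78.12,78.6,76.94
2,24.37,23.26,26.58,26.17,33.36,39.4,42.74,52.1,57.23,64.92,71.4,75.04,80.91,85.64,86.68,88.48,90.2,29.28,35.79,37.79,43.78,48.55,65.64,69.65,76.52,78.16,85.09,54.95,58.43,56.69,56.85,49.15,53.01,56.54,60.86,63.4,45.8,41.58,35.98,33.98,35.15,39.92,81.3,80.07,70.08,68.41,73.85,78.66,71.61,67.84,65.45,57.38,48.24,45.76,41.49,43.68,48.06,57.1,65.44,68.37,65.23,63.81,57.37,50.66,47.38,52.46,57.43,62.12,51.66,59.15,68.01,75.67,80,85.5,88.89,90.46,89.85,92.57,89.33,85.83,81.48,74.29,67.38,62.59,52.65,33.73,30.83,30.87,33.27,33.17,33.55,30.32,31.45,29.28,32.78,43.05,44.71,52.14,56.08,58.11,61.08,60.76,63.06,58.64,42.27,39.53,40.85,42.51,43.83,41.68,41.55,39.35,37.8,40.37,43.31,43.18,75.78,70.48,68.81,68.76,70.02,72.12,77.27,80.46,81.52,84.13,83.29,79.17,76.57,71.72,74.78,72.74,76.69,78.62,78.78,76.22
3,25.6,24.37,26.83,28.65,34.09,37.44,43.56,51.26,55.94,62.79,70.84,75.56,78.77,84.59,86.86,88.71,90.54,30.01,34.78,38.33,41.95,48.19,68.46,69.99,75.91,78.02,84.05,57.28,55.98,58.03,57.42,48.21,51.59,57.15,61.07,63.88,45.63,41.58,34.94,30.15,33.32,40.76,82.99,77.21,70.87,70.86,72.36,77.55,70.73,69.06,64.65,57.16,49.65,42.85,42.98,43.02,51.12,58.06,64.62,68.33,65.08,62.42,57.23,49.32,47.73,49.97,57.37,63.41,49.61,56.82,68.25,73.58,77.97,84.19,87.48,89.13,91.29,89.88,87.71,84.75,79.89,73.06,67.06,61.36,50.11,31.42,31.1,30.28,31.36,32.92,33.54,31.05,30.19,30.32,33.85,38.28,43.89,51.62,55.94,57.32,59.56,61.19,57.78,58.96,38.68,39.96,37.8,39.33,41.81,41.17,41.34,39.15,37.82,39.24,41.44,40.24,75.19,72.71,68.39,66.4,68.42,71.46,76.3,79.64,82.07,83.35,82.42,77.21,74.77,71.17,69.97,69,74.64,76.22,78.81,77.9
4,21.09,24.88,23.86,26.11,32.81,37.42,43.79,49.28,54.2,63.23,67.44,74.3,79.98,83.02,85.99,86.96,87.65,27.05,32.96,35.85,41.82,45.39,64.57,68.6,73.07,77.41,83.35,55.53,55.23,54.25,53.15,48.18,51.27,55.18,59.15,62.13,43.04,40.23,34.52,30.44,35.27,39.19,81.08,77.22,68.81,67.48,71.27,77.02,68.29,66.94,62.51,56.52,46.61,42.62,39.82,41.78,47.7,56.22,63.11,66.77,63.73,61.6,54.16,49.37,45.34,49.86,54.62,60.11,48.19,57.74,65.74,73.32,76.94,82.3,85.67,90.13,88.11,85.7,85.62,81.76,79.56,70.15,63.6,57.72,51.85,31.36,30.15,30.22,29.59,28.86,31.22,26.82,26.93,28.92,30.62,37.78,43.24,48.38,53.28,58.11,56.51,57.05,59.06,56.31,36.2,36.58,36.3,36.8,41.49,39.15,38.3,33.68,35.78,37.5,37.5,41.09,74.17,68.47,65.5,64.75,66.52,67.78,72.7,77.27,82.18,81.25,79.33,77.5,73.58,69.39,70.31,68.52,72.44,76.14,76.87,74.6
5,21.7,24.77,27.43,28.24,32.23,39.18,41.76,50.12,56.8,64.76,70.48,76.79,80.9,82.8,88.06,89.1,90.11,31.23,35.2,41.27,43.63,48.17,66.85,69.82,76.27,78.59,85.83,55.05,57.14,56.12,57.46,48.53,52.7,57.35,60,64.87,44.5,43.46,35.18,31.89,33.92,40.59,80.93,77.91,70.82,68.67,70.94,77.22,68.77,68.3,65.88,56.9,49.86,44.16,43.18,43.99,50.02,55.85,64.56,70.43,65.61,63.7,56.69,49.34,47.68,50.35,55.18,63.15,49.11,58.26,65.84,73.41,79.6,83.73,86.45,91.1,90.49,87.35,88.07,83.56,79.81,73.18,65.03,57.93,49.68,31.96,30.8,29.92,29.7,32.26,31.65,31.63,28.55,30.72,31.48,40.82,44.41,49.83,56.16,58.44,60.12,60.36,60.32,59.32,40.01,39.79,37.74,39.51,41.66,41,41.24,37.35,37.21,38.82,42.1,42.45,74.49,70.37,69.34,68.26,66.08,69.79,75.34,80.19,82.88,83.16,80.72,77.63,74.3,71.56,71.3,72.39,75.5,77.38,76.13,77.3
6,23.17,23.43,24.61,27.67,30.86,37.14,41.64,49.16,55.02,62.57,67.79,74.69,78.85,83.19,86.4,88.96,87.84,28.6,32.37,38.09,42.43,46.13,63.7,68.98,74.39,78.64,83.15,54.24,55.66,56.9,54.66,49.35,49.94,54.1,60.35,62.35,44.63,40.23,33.66,30.79,34.54,39.25,81.58,77.44,69.6,67.86,70.01,77.56,69.06,67.49,63.65,56.8,48.57,42.27,41.86,41.72,50.24,55.25,62.31,67.33,65.55,60.9,54.21,46.83,44.15,49.42,55.12,61.21,52.48,58.6,65.82,75.39,78.48,84.12,87.47,91.58,91.21,92.26,90,85.59,82.55,72.07,66.09,61.09,52.85,32.02,32.3,31.56,30.12,33.45,33.45,31.39,28.3,32.42,33.01,38.81,43.49,50,57.23,60.9,60.23,62.64,59.87,56.06,40.82,39.47,39.64,39.4,43.14,43.17,39.57,38.93,36.1,40.03,43.77,41.28,75.95,69.76,68.98,67.15,68.58,71.37,76.51,80.75,82.39,83.69,83.74,79.03,74.19,72.51,71.35,72.82,76.35,77.62,78.8,77.62
7,23.87,23.66,21.88,26.13,32.17,36.15,41.75,48.04,56.43,62.23,68.59,73.89,78.65,84.45,86.32,87.75,89.63,27.08,33.25,37.72,42.58,46.51,64.27,68.14,73.01,78.02,83.75,55.11,56.99,55.56,55.17,47.91,50.6,54.31,58.31,63.81,42.96,40.38,34.49,29.74,33.81,41.42,81.5,75.19,68.28,67.32,69.29,78.05,67.82,67.06,63.15,55.67,45.62,42.26,41.94,43.02,49.23,54.64,63.18,68.87,64.3,63.29,55.57,50.66,46.51,48.13,55.95,61.61,51.69,59.99,67.16,73.35,80.27,84.12,87.66,89.59,90.48,90.68,89.34,85.31,80.5,73.8,64.65,59.96,52.47,33.17,29.77,30.24,30.46,33.71,32.46,31.96,29.56,31.82,33.28,39.57,43.66,49.82,54.35,58.62,59.3,60.86,61.82,57.62,41.31,38.65,38.05,39.24,41.6,41.54,38.93,37.28,38.96,38.63,43.42,41.79,77.19,72.34,70.04,68.2,67.78,70.69,76.86,76.82,81.51,83.18,83.04,76.23,74.83,73.32,72.08,71.87,75.48,77.23,78.87,77.17
8,24.57,25.26,24.18,28.82,33.46,38.56,43.35,48.41,57.27,63,69.51,73.4,81.08,84.01,86.82,90.35,91.64,29.44,35.66,39.5,46,47.53,68.52,70.36,74.72,80.54,85.75,56.29,55.99,57.36,56.12,47.42,52.34,56.31,61.46,66.09,45.23,42.56,37.23,32.43,34.89,42.72,82.8,79.43,72.94,67.61,71.02,77.53,70.51,69.56,67.04,56.81,47.87,43.14,41.75,44.68,50.89,59.45,63.37,71.94,64.55,64.74,56.24,48.61,48.19,50.38,55.83,63.42,50.46,56.82,67.81,74.74,78.94,85.11,87.97,91.91,91.1,90.84,89.59,85.92,79.55,74.81,65.34,58.85,52.52,31.89,31.26,31.35,31.53,32.46,32.99,32.14,29.79,30.94,33.83,39.16,44.04,51.53,55.57,58.85,62.01,58.95,61.14,59.25,40.12,37.98,38.71,40.05,42.36,43.42,40.82,39.47,39.27,39.7,44.08,42.69,74.93,71.64,69.52,69.29,68.18,73.74,77.64,78.3,83.04,83.48,82.51,78.03,77.08,72.95,73.06,71.49,76.94,78.36,79.14,76.95
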