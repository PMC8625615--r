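"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,22.17,20.51,22.81,26.24,31.37,36.39,42.27,50.22,57.7,66.61,70.94,78.03,86.13,89.39,92.12,94.95,94.52,24.98,32.42,35.45,40.24,47.44,68.62,73.16,77.54,83.67,89.04,55.4,56.66,56.56,57.64,49.99,50.66,58.89,61.12,66.57,44.47,40.23,34.61,31.27,34.17,39.67,82.68,82.94,76.64,70.32,74.55,82.29,73.44,72.66,64.22,57.99,49.01,43.81,40.15,44.01,47.19,56.87,67.07,71.6,68.33,65.24,60.21,49.58,48.53,48.89,57.75,63.46,52.74,60.2,66.97,75.82,84.83,87.16,91.79,96.08,95.61,94,93.71,90.36,80.77,76.35,66.68,56.91,51.72,29.67,28.39,28.5,29.17,31.27,28.97,28.56,27.08,31.96,31.51,38.51,43.25,47.85,56.11,61.78,59.72,60.86,62.32,58.36,40.28,37.56,37.59,39.82,42.8,40.5,39,35.32,35.25,41.36,41.23,40.04,71.68,70.16,65.2,65.5,66.92,68.79,73.53,77,80.63,81.51,81.3,78.39,73.73,70.9,69.26,71.11,74.14,75.8,78.14,76.26
2,22.49,23.8,25.53,26.03,29.95,36.51,44.74,50.12,60.15,67.04,71.3,79.23,86.03,88.81,94.38,94.51,96.8,27.7,32.38,36.78,42.09,48.95,67.18,74.24,77.37,83.45,89.76,57.92,58,57.79,59.4,49.76,53.54,60.31,62.98,68.28,43.33,41.1,34.95,31.69,32.34,41.93,84.04,82.9,77.17,71.87,74.42,82.86,74.01,71.44,67.97,57.29,51.35,44.01,42.98,44.56,50.04,57.05,66.16,72.75,67.69,64.05,56.76,52.97,50.55,48.73,58.18,65.02,49.73,58.79,67.38,76.05,82.88,88.13,91.86,95.21,93.91,95.5,92.29,87.71,82.74,76.4,67.98,58.38,50.08,30.26,28.42,26.1,28.27,29.21,31.66,27.34,27.8,29.99,30.51,38.79,43.39,48.64,54.94,58.73,60.17,61,59.47,59.58,37.79,36.26,37.05,37.67,42.19,40.58,39.49,36.64,36.51,40.28,42.36,41.43,73.48,70.57,66.81,65.99,66.91,70.54,74.09,77.06,80.32,83.23,81.26,79.89,73.88,72.99,70.93,71.32,74.39,79.35,77.97,78.68
3,21.66,21.18,26.46,27.41,31,38.37,43.65,51.29,58.85,66.33,72.52,78.6,84.48,89.56,92.24,95.41,95.61,25.11,33.23,37.66,42.02,49.34,69.36,73.79,78.43,85.17,88.11,59.54,56.14,58.61,57.61,48.61,55.35,59.29,62.27,64.72,45.96,40.64,33.87,31.38,31.89,40.77,83.93,82.33,74.73,71.89,76.16,84.23,73.58,72.71,64.61,57.75,50.82,45.12,42.13,45.34,51.3,58.45,67.13,72.14,69.71,65.69,57.99,51.88,48.49,51.29,58.44,65.61,49.3,59.62,67.95,76.56,83.19,86.06,88.51,93.7,93.92,93.97,93.3,87.47,80.99,75.73,67.73,56.66,48.79,28.45,27.62,27.4,28.69,28.11,29.41,28.22,26.24,26.16,30.97,38.75,41.15,50.05,53.5,58.6,59.37,57.31,58.24,56.86,38.06,37.42,36.84,36.25,40.87,41.03,38.39,35.4,35.08,38.68,40.55,39.64,71.91,65.94,67.95,64.04,65.62,67.72,75.02,77.61,81.22,81.34,81.05,77.7,71.75,71.58,67.98,71.54,74.45,76.62,76.27,75.09
4,17.37,19.5,21.22,23.24,29.61,35.86,41.11,47.08,54.72,61.97,70.53,76.06,80.42,85.84,89.18,92.97,90.9,24.45,29.74,33.84,40.31,44.33,65.48,73.38,75.41,81.07,85.68,57.18,54.44,55.46,55.87,47.24,51.9,56.8,60.53,65.23,43.14,38.38,31.11,27.5,31.99,39.63,80.98,79.23,73.76,68.54,73.05,80.02,72.39,69.08,62.87,53.15,47.54,39.99,39.19,39.83,47.44,55.64,62.79,68.91,65.48,62.78,53.92,47.87,44.93,46.77,54.6,61.57,47.13,58.26,66.58,74.26,81.17,85.27,90.78,94.03,93.43,92.24,91.77,86.08,79.49,75.2,66.25,56.64,47.99,28.53,27.25,28.28,27.88,28.72,27.68,25.95,25.76,27.16,28.31,37.17,43.07,47.42,54.2,56.4,58.96,60.45,59.53,56.68,38.25,34.28,35.97,36.06,39.15,40.09,37.05,34.61,33.04,37.68,39.63,39.27,71.52,66.84,65.06,63.72,65.11,66.35,71.03,75.45,78.92,80.31,79.31,75.15,70.03,71.02,66.98,70.84,71.08,75.08,73.79,74.45
5,17.49,19.49,21.58,23.89,29.7,34.07,41.3,48.53,53.8,62.6,68.48,76.8,80.63,87.68,88.87,90.48,92.4,26,30.53,33.85,38.92,46.27,65.27,71.67,74.8,80.44,86.5,53.75,53.3,54.87,57.28,48.14,49.07,58.61,58.37,62.59,42.92,37.69,31.4,27.58,30,38.49,82.53,78.45,73.74,69.7,73.19,80.21,72.6,68.73,63.96,53.18,48.15,41.44,37.84,41.27,47.94,55.81,62.47,69.79,65.6,61.9,54.72,47.14,45.22,45.97,53.89,62.02,49.66,59.71,65.85,72.77,82.7,86.32,89.52,96.01,93.59,94.11,93.23,88.78,81.57,72.13,67,57.91,49.02,29.21,28.94,26.71,26.44,26.52,29.99,27.88,24.76,27.46,28.53,36.09,42.69,49.22,54.11,57.36,59.95,61.1,60.11,56.75,37.92,34.83,36.59,38.02,40.13,40.61,37.95,34.07,35.98,37.3,40.38,39.07,71.82,69.59,65.37,63.41,65.19,67.71,73.38,76.18,79.83,80.03,79.01,75.58,73.41,69.98,69.23,69.45,72.52,76.76,76.84,75.98
6,18.25,19.68,21.86,24.21,27.81,35.46,41.08,48.56,55.73,60.92,68.56,76.44,83.76,87.27,89.59,92.62,91.86,22.65,32.17,35.22,38.44,44.97,66.35,72.67,76.53,80.35,85.17,54.22,53.81,56.38,57.17,47.27,50.62,56.48,58.66,64.44,46.34,37.6,32.35,29.71,31.28,37.6,82.74,80.16,73.21,67.75,72.99,80.23,70.12,68.9,64.44,56.03,47.56,43.27,39.06,42.23,47.85,55.97,62.9,69.71,66.88,62.29,55.14,47.92,44.84,48.32,55.51,61.48,47.91,57.82,67.39,74.16,80.57,85.54,90.48,92.41,91.86,94.02,91.39,87.51,79.31,74.99,66.21,56.99,49.08,27.75,24.55,25.86,26.75,27.09,30.25,26.51,24.06,26.65,28.08,36.06,42.49,47.96,53.73,59.95,59.09,60.74,57.66,57.62,37.31,35.39,35.68,36.95,41.33,39.13,38.68,34.81,32.18,37.14,39.65,39.88,70.89,67.97,63.69,63.17,66.29,68.62,74.17,76.82,79.43,79.52,78.78,76.46,70.94,67.93,68.32,70,71.57,75.2,75.82,75.17
7,17.39,17.26,20.78,24.75,29.15,35.16,41.2,47.43,55.12,62.72,69.3,74.92,80.89,85.54,89.3,91.69,91.87,23.45,29.93,33.04,38.51,45.62,65.99,71.68,74.51,79.87,87.5,54.1,55.27,56.91,56.58,47.27,49.73,54.39,58.67,64.92,41.34,39.69,31.82,29.66,31.99,38.58,83.03,78.95,72.31,70.98,71.64,79.46,71.68,68.46,62.05,53.66,50.14,39.92,37.78,41.79,47.75,53.59,63.13,68.74,65.26,62.58,57.07,48.01,45.34,47.65,55.77,61.14,49.27,58.22,66.88,74.62,82.15,85.9,89.16,93.78,93.31,93.5,92.55,87.34,81.36,73.61,66.49,56.64,48.93,26.8,25.38,28.04,26.75,28.3,28.45,26.1,26.27,25.81,27.85,37.24,41.24,46.16,53.8,56.5,58.36,60.29,57.33,56.69,37.09,34.82,35.37,37.96,39.93,39.26,38.06,35.42,32.77,37.32,41.69,37.71,71.8,68.35,67.1,64.03,64.61,67.69,72.89,74.85,78.4,80.17,77.4,76.36,72.41,67.78,67.52,69.76,72.02,74.9,75.62,75.22
8,20.01,19.31,23.59,25.69,30.91,36.25,42.91,51.25,56.74,64.83,69.33,77.43,84.93,89.14,91.77,93.86,94.67,25.21,31.68,36.64,40.53,49.38,67.81,75.82,74.38,83.29,88.17,57.11,55.57,55.81,59.53,51.35,52.62,60.96,62.6,64.3,44.39,39.69,34.43,29.42,32.29,41.86,83.87,82.07,74.69,70.89,74.3,81.93,75.45,73.15,65.68,57.45,51.09,45.74,40.48,42.76,49.41,57.65,65.45,71.66,68.98,62.97,59.63,51.11,47.3,49.17,55.6,64.79,50.71,58.15,67.11,74.22,83,87.79,89.89,92.91,94.86,94.77,92.35,90.44,82.06,76.2,66.32,58.11,50.62,30.31,27.2,27.08,27.87,30.7,28.22,27.82,27.57,28.43,30.93,36.26,42.59,47.17,53.91,59.35,59.49,61.43,60.5,58.88,38.94,35.51,35.18,37.74,40.13,39.32,39.28,36.43,35.55,38.35,41.43,40.18,72.68,69.96,67.09,66.42,67.56,69.97,73.54,77.76,80.66,83.38,81.64,76.24,74.23,69.13,69.58,73.16,74.33,79.04,77.21,77.68
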