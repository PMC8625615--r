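"frame","x1","x2","x3","x4","x5","x6","x7","x8","x9","x10","x11","x12","x13","x14","x15","x16","x17","x18","x19","x20","x21","x22","x23","x24","x25","x26","x27","x28","x29","x30","x31","x32","x33","x34","x35","x36","x37","x38","x39","x40","x41","x42","x43","x44","x45","x46","x47","x48","x49","x50","x51","x52","x53","x54","x55","x56","x57","x58","x59","x60","x61","x62","x63","x64","x65","x66","x67","x68","y1","y2","y3","y4","y5","y6","y7","y8","y9","y10","y11","y12","y13","y14","y15","y16","y17","y18","y19","y20","y21","y22","y23","y24","y25","y26","y27","y28","y29","y30","y31","y32","y33","y34","y35","y36","y37","y38","y39","y40","y41","y42","y43","y44","y45","y46","y47","y48","y49","y50","y51","y52","y53","y54","y55","y56","y57","y58","y59","y60","y61","y62","y63","y64","y65","y66","y67","y68"
1,20.33,20.67,23.01,27.2,32.33,37.99,41.61,48.97,55.93,65.47,72.05,78.25,83.91,90.43,91.68,94.54,95.18,27.72,34.03,35.35,42.5,48.57,68.91,72.79,75.69,85.38,88.36,58.07,58.65,55.06,58.48,50.4,52.6,59.95,62.98,65.7,47.01,39.9,34.72,32.12,33.73,41.11,84.52,82.57,74.92,73.16,74.38,81.59,74.5,70.55,65.43,56.66,48.55,43.81,39.84,43.27,49.24,56.73,66.27,71.59,67.97,65.5,57.16,50.2,48.19,49.34,57.68,65.39,50.23,59.31,66.79,76.35,82.18,89.16,91.32,94,94.4,94.35,94.62,85.46,80.45,74.84,66.88,55.03,50.95,28.01,26.76,29.03,26.68,28.69,28.89,27.25,28.57,28.31,28.36,38.58,42.64,48.5,53.33,58.02,62.01,61.11,58.61,58.9,38.4,35,35.72,37.89,41.42,38.19,36.57,36.34,35.16,37.45,42.08,39.75,74.38,72.47,67.49,67.8,67.56,72.38,74.45,77.78,81.86,83.01,82.54,78.51,74.7,71.53,71.18,74.88,75.08,79.46,79.51,77.12
2,19.39,20.38,22.55,23.08,31.49,36.23,42.79,51.19,54.68,64.65,70.42,76.18,82.91,89.49,90.75,92.22,94.56,24.72,32.57,35.81,41.25,46.98,68.84,72.35,75.6,81.78,88.86,57.67,56.24,56.09,57.12,48.92,53.91,59.04,59.01,64.16,44.28,41.24,33.05,31.04,33.75,39.98,82.44,81.32,73.75,71.63,74.33,81.29,74.25,70.33,65.33,58.22,49.95,41.53,40.19,42.69,50.27,55.28,64.08,72.01,68.19,64.52,56.43,50.53,48.22,48.65,56.47,64.82,48.47,57.74,64.97,75.31,79.77,86.24,89.54,92.85,90.66,92.67,89.06,86.27,79.7,73.1,64.39,55.87,49.45,27.13,24.32,25.29,25.99,26.25,29.06,26.73,24.86,26.52,26.46,35.57,40.16,47.76,52.2,58.88,57.31,59.86,57.39,55.63,37.18,34.12,34.56,36.25,38.17,36.55,37.38,34.27,33.58,36.48,38.54,37.94,72.66,69.71,66.02,64.77,66.17,68.53,74.6,78.62,80.04,82.02,80.49,77.26,73.26,69.64,68.06,71.63,74.42,77.67,76.52,77.53
3,20.6,21.69,25.25,26.58,28.86,36.95,42.89,48.79,55.56,66.44,72.39,76.85,83.28,88.65,92.4,95.76,97.41,25.45,32,35.71,42.97,47.53,67.56,73.11,78.04,81.98,90.6,56.57,55.09,57.38,59.03,48.6,53.53,56.7,62.88,67.59,45.29,41.43,35.71,29.88,33.64,39.31,83,82.83,74.74,70.39,73.57,82.41,73.17,72,65.53,58.04,48.68,45.17,41.53,43.65,49.14,57.55,65.71,73,68.96,64.88,58.55,50.46,48.5,51.11,58.21,64.03,49.21,62,67.68,74.29,81.85,89.11,90.1,95.08,94.99,94.33,93.21,90.4,83.06,76.3,69.35,57.52,49.78,31.19,27.98,26.46,28.77,29.92,28.45,27.04,26.91,27.86,28.9,38.35,44.66,49.71,55.18,59.4,58.44,62.03,60.19,58.52,38.81,37.48,38.83,38.55,41.67,42.32,37.98,36.74,34.8,38.69,42.55,41.83,72.79,67.48,67.17,66.7,67.07,68.89,72.39,76.72,81.44,82.83,80.55,78.54,72.45,69.93,70,72.32,74.07,77.89,76.05,77.36
4,20.43,19.5,20.57,26,30.69,35.21,41.32,48.79,55.52,64.71,68.49,77.08,82.78,88.03,89.95,92.15,92.24,25.96,31.15,34.24,43.01,46.5,68.44,72.67,74.65,80.92,87.85,53.56,56.3,53.13,58.05,48.74,51.54,58.22,59.63,63.64,43.49,38.87,32.73,27.32,31.82,40.61,82.76,79.4,73.51,69.41,71.58,80.79,73.34,70.24,63.14,56.05,47.88,43.84,40.99,41.17,48.42,54.85,65.14,70.28,66.02,61.83,56.86,48.88,45.17,45.87,55.32,61.9,48.01,56.9,67.89,75.25,81.67,86.07,89.36,93.97,92.47,92.96,91.49,86.18,79.94,75.08,64.5,57.68,49.43,28.23,26.18,25.03,27.7,27.16,27.07,26.2,24.33,26.2,27.17,36.32,41.74,46.76,52.43,57.5,57.74,59.59,57.78,55.92,37.11,33.57,35.09,35.23,37.89,40.31,35.15,34.48,33.54,37.82,39.14,38.02,69.65,67.12,62.88,62.77,64.07,66.82,72.85,75.94,78.78,78.54,79.96,74.36,72.9,68.63,67.01,68.05,71.75,77.17,75.15,76.28
5,17.99,18.97,20.97,24.91,30.83,33.59,41.37,48.25,54.33,61.82,68.38,74.52,82.44,87.09,91.22,92.48,91.55,21.43,29.79,34.46,38.74,43.84,65.08,70.75,74.17,80.53,86.86,55.19,55.84,55.97,56.38,47.27,49.58,55.06,58.65,64.6,41.5,38.22,32.65,28.66,30.84,37.99,81.31,79.63,74.04,69.5,70.73,80.49,70.46,67.87,64.13,55.75,47.32,40.51,40.15,41.59,46.01,52.78,64.59,69.73,64.94,61.7,56.52,48.82,45.61,50.55,54.29,60.27,51.95,59.32,70.34,77.12,83.51,87,91.39,95.18,93.33,94.58,94.04,88.01,82.56,74.32,66.85,57.35,50.89,29.14,28.28,27.24,29.88,27.75,29.72,27.01,28.57,27.41,28.99,37.2,43.85,49.91,56.23,58.3,60.76,60.07,59.6,59.38,38.77,37.12,37.36,38.63,43.02,39.95,38.7,34.26,37.92,40.35,39.7,39.63,74.75,71.59,67.04,67.33,71.01,72.1,77.8,80.28,79.9,84.86,83.04,78.11,74.85,70.51,73.14,73.77,76.9,77.05,79.2,78.21
6,17.66,16.96,22.75,23.15,27.38,33.03,41.37,47.34,53.79,61.9,68.98,75.28,79.83,85.86,89.16,90.83,93.48,23.07,28.79,33.71,38.84,42.9,63.16,71.16,74.05,80.73,85.9,56.05,55.95,54.22,56.27,45.59,50.28,55.97,56.44,63.17,41.7,38.22,31.9,26.78,31.31,37.76,80.49,79.43,70.77,68.05,70.62,79.06,72.27,68.33,62.16,55.77,47.73,39.98,38.46,38.83,45.17,53.71,62.06,69.51,65.02,64.05,54.26,46.72,42.59,44.73,53.94,61.04,50.27,58.4,66.53,75.03,83.96,85.87,90.07,95.59,93.47,93.34,91.07,88.67,84.39,75,64.83,57.36,50.1,27.24,25.88,25.66,26.41,27.54,30.61,25.97,25.3,27.45,28.25,38.45,42.09,48.82,55.14,59.97,57.9,59.73,60.05,57.95,35.87,35.8,33.98,36.56,39.57,39.1,36.85,33.47,33.65,39.5,38.4,39.59,75.93,69.15,67.22,65.44,67.73,71.43,74.54,75.97,81.51,82.36,82.46,77.25,73.57,70.7,70.69,73.72,74.17,76.69,79.56,80.16
7,16.53,17.91,22.35,24.96,29.4,32.9,39.69,47.08,53.26,61.62,67.42,77.66,82.21,86.42,90.1,91.63,92.76,24.75,29.51,32.83,40.35,45.3,65.64,70.96,75.55,81.37,86.79,55.1,54.19,54.57,55.87,46.42,51.7,55.02,56.85,64.13,42.52,36.94,31.52,26.69,29.09,38.58,79.86,79.78,71.46,67.22,71.28,81.72,70.92,68.68,64.33,55,48.15,41.75,38.21,41.08,46.51,55.01,63.48,68.89,63.6,62.09,54.44,48.33,44.08,47.03,55.74,62.67,51.64,61.16,69.02,73.51,83.47,88.89,89.93,94.65,95.22,93.09,94.41,88.6,83.75,75.25,66.85,58.28,49.29,28.88,28.51,27.67,26.8,32.25,30.3,26.66,27.07,26.53,27.5,36.98,43.46,48.79,54.68,59.07,59.21,61.04,59.45,59,38.5,34.88,35.66,37.35,40.51,39.15,39.11,34.75,35.66,38.64,40.03,39.23,73.5,68.91,67.31,65.94,69.96,71.35,76.85,80.04,80.76,84.59,82.85,79.61,75.46,74.53,71.79,73.23,74.87,78.48,79.4,78.51
8,17.21,18.63,21.17,23.91,30.39,34.04,41.57,48.29,56.46,63.11,70.53,77.02,84.72,86.39,91.07,92.65,94.65,24.54,30.87,35.41,41.07,44.92,65.69,71.91,75.13,80.2,86.25,55.49,55.82,55.26,56.03,49.68,51.27,56.39,59.08,64.49,42.06,40.47,32.37,28.44,33.3,39.17,82.48,79.31,72.55,67.07,72.46,81.06,71.12,71.76,63.74,53.84,47.54,41.49,38.59,41.66,48.35,56.04,65.7,71.98,65.37,62.93,53.42,46.98,45.83,47.59,55.45,63.86,51.6,60.25,68.12,76.58,81.71,89.33,92.12,97.31,95.31,96.09,92.85,90.76,83.37,77.59,67.39,57.74,48.94,30.66,28.55,29.27,29.94,31.13,29.15,28.61,25.98,28.69,28.85,38.89,45.01,48.04,55.62,60.28,61.77,63.02,60.01,60.32,39.43,37.26,36.07,38.02,40.57,41.89,38.88,37.44,36.67,39.38,41.2,41.92,71.74,69.53,67.8,66.57,68.26,69.03,74.49,78.06,80.22,82.54,81.09,76.68,74.44,71.31,69.7,70.76,74.8,77.36,76.88,76.97
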